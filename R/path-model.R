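# Recursive construct-level path analysis. Constructs are unit-weighted
# composites of sign-aligned z-scored indicators; each endogenous construct
# is regressed on its parents (the ML solution for a recursive system with
# uncorrelated errors on standardized data). Standardized effects decompose
# through the direct-coefficient matrix B: total = (I - B)^-1 - I,
# indirect = total - direct.

#' Construct specification: indicators with orientation signs
#'
#' @param constructs named list; each element is a named numeric vector of
#'   orientation signs (+1 / -1) keyed by indicator column name.
#' @return object of class `construct_spec`.
#' @export
construct_spec <- function(constructs) {
  all_ind <- unlist(lapply(constructs, names))
  if (anyDuplicated(all_ind)) {
    abort("indicator(s) assigned to more than one construct: %s",
          paste(unique(all_ind[duplicated(all_ind)]), collapse = ", "))
  }
  signs <- unlist(constructs)
  if (!all(signs %in% c(-1, 1))) abort("orientation signs must be +1 or -1")
  structure(constructs, class = "construct_spec")
}

#' Default construct specification
#'
#' Human, physical and social capital indicators, the medical-services
#' utilization block, and the vulnerability index as a single-indicator
#' construct. The default follows the modified model in which the outpatient
#' out-of-pocket and physical-examination indicators are dropped from the
#' utilization block; `modified = FALSE` restores the initial full set.
#'
#' @param modified use the respecified indicator set (default TRUE).
#' @param vulnerability_col column name holding the vulnerability index.
#' @return a [construct_spec()].
#' @export
default_construct_spec <- function(modified = TRUE,
                                   vulnerability_col = "vulnerability") {
  util <- c(outpatient = 1, inpatient = 1, inpatient_oop_log = 1,
            self_treatment = 1)
  if (!modified) {
    util <- c(util, outpatient_oop_log = 1, physical_examination = 1)
  }
  construct_spec(list(
    human = c(educational_level = 1, health_status = 1, labor_force = 1,
              migrant_workers = 1),
    physical = c(agri_machines = 1, durable_products = 1,
                 building_material = 1, tap_water = 1, latrines_type = 1,
                 cultivated_area = 1, sep_housing_kitchen = 1),
    social = c(cash_gift_log = 1),
    utilization = util,
    vulnerability = setNames(1, vulnerability_col)))
}

#' Directed acyclic path diagram over constructs
#'
#' @param edges data.frame with columns `from` and `to` (construct names), or
#'   a list of length-2 character vectors.
#' @param nodes optional explicit node set; defaults to all edge endpoints.
#' @return object of class `path_diagram` with topologically ordered nodes.
#' @export
path_diagram <- function(edges, nodes = NULL) {
  if (is.list(edges) && !is.data.frame(edges)) {
    edges <- data.frame(from = vapply(edges, `[`, character(1), 1),
                        to = vapply(edges, `[`, character(1), 2),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("from", "to") %in% names(edges)))
  if (is.null(nodes)) nodes <- unique(c(edges$from, edges$to))
  if (!all(edges$from %in% nodes) || !all(edges$to %in% nodes)) {
    abort("edge endpoint not in the declared node set")
  }
  if (anyDuplicated(paste(edges$from, edges$to))) abort("duplicated edge")
  # Kahn's algorithm: topological order, errors on a cycle
  order <- character(0)
  remaining <- edges
  pending <- nodes
  while (length(pending) > 0) {
    free <- pending[!pending %in% remaining$to]
    if (length(free) == 0) abort("path diagram contains a cycle")
    order <- c(order, free)
    remaining <- remaining[!remaining$from %in% free, , drop = FALSE]
    pending <- setdiff(pending, free)
  }
  structure(list(nodes = order, edges = edges[, c("from", "to")]),
            class = "path_diagram")
}

#' Default path diagram
#'
#' Human capital drives physical capital and utilization; physical capital
#' drives social capital; all four constructs point at vulnerability.
#'
#' @return a [path_diagram()].
#' @export
default_path_diagram <- function() {
  path_diagram(data.frame(
    from = c("human", "physical", "human", "human", "physical", "social",
             "utilization"),
    to = c("physical", "social", "utilization", "vulnerability",
           "vulnerability", "vulnerability", "vulnerability"),
    stringsAsFactors = FALSE))
}

zscore <- function(x, name) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) abort("constant indicator: %s", name)
  (x - mean(x)) / s
}

#' Build standardized construct composites
#'
#' Each composite is the mean of its sign-aligned z-scored indicators,
#' re-standardized to zero mean and unit variance.
#'
#' @param table data.frame holding all indicator columns.
#' @param spec a [construct_spec()].
#' @return data.frame of composites, one column per construct.
#' @export
build_composites <- function(table, spec) {
  stopifnot(inherits(spec, "construct_spec"))
  out <- lapply(names(spec), function(k) {
    signs <- spec[[k]]
    missing_ind <- setdiff(names(signs), names(table))
    if (length(missing_ind) > 0) {
      abort("indicator(s) for construct '%s' not in table: %s", k,
            paste(missing_ind, collapse = ", "))
    }
    z <- vapply(names(signs),
                function(v) signs[[v]] * zscore(as.numeric(table[[v]]), v),
                numeric(nrow(table)))
    zscore(rowMeans(z), paste0("composite:", k))
  })
  names(out) <- names(spec)
  as.data.frame(out)
}

# direct-coefficient matrix B with B[child, parent] = edge coefficient
edge_matrix <- function(edges, nodes) {
  B <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    B[edges$to[i], edges$from[i]] <- edges$estimate[i]
  }
  B
}

fit_path_once <- function(composites, diagram) {
  edges <- diagram$edges
  edges$estimate <- NA_real_
  psi <- setNames(numeric(length(diagram$nodes)), diagram$nodes)
  for (node in diagram$nodes) {
    parents <- edges$from[edges$to == node]
    if (length(parents) == 0) {
      psi[node] <- mean(composites[[node]]^2)
      next
    }
    Xp <- as.matrix(composites[parents])
    check_full_rank(Xp, sprintf("parent set of '%s'", node))
    f <- lm.fit(cbind(1, Xp), composites[[node]])
    edges$estimate[edges$to == node] <- f$coefficients[-1]
    psi[node] <- mean(f$residuals^2)
  }
  list(edges = edges, psi = psi)
}

#' Fit a recursive path model on standardized composites
#'
#' @param composites data.frame from [build_composites()] (each column is
#'   standardized).
#' @param diagram a [path_diagram()] whose nodes are composite columns.
#' @param bootstrap_reps paired-bootstrap replications for edge standard
#'   errors (composites are re-standardized within each resample); 0 skips.
#' @param seed bootstrap seed.
#' @param coefficient_cap absolute standardized-coefficient value above which
#'   an edge is flagged (composite-model artifact); default 1.
#' @return object of class `path_fit`: edge table (estimate, se, cr, p,
#'   stars), residual variances, sample covariance of the composites, n.
#' @export
fit_path_model <- function(composites, diagram, bootstrap_reps = 500,
                           seed = 13L, coefficient_cap = 1) {
  stopifnot(inherits(diagram, "path_diagram"))
  missing_nodes <- setdiff(diagram$nodes, names(composites))
  if (length(missing_nodes) > 0) {
    abort("composite column(s) missing: %s",
          paste(missing_nodes, collapse = ", "))
  }
  composites <- composites[diagram$nodes]
  n <- nrow(composites)
  point <- fit_path_once(composites, diagram)
  edges <- point$edges

  edges$se <- NA_real_
  if (bootstrap_reps > 0) {
    set.seed(as.integer(seed))
    draws <- matrix(NA_real_, bootstrap_reps, nrow(edges))
    for (r in seq_len(bootstrap_reps)) {
      idx <- sample.int(n, n, replace = TRUE)
      resamp <- as.data.frame(lapply(composites[idx, , drop = FALSE],
                                     zscore, name = "bootstrap composite"))
      draws[r, ] <- fit_path_once(resamp, diagram)$edges$estimate
    }
    edges$se <- apply(draws, 2, sd)
  }
  edges$cr <- edges$estimate / edges$se
  edges$p_value <- 2 * pnorm(-abs(edges$cr))
  edges$flagged <- abs(edges$estimate) > coefficient_cap
  structure(list(edges = edges, psi = point$psi,
                 S = stats::cov(composites) * (n - 1) / n,
                 n = n, diagram = diagram,
                 bootstrap_reps = bootstrap_reps, seed = seed),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat("Recursive path model (n =", x$n, ")\n")
  tab <- x$edges
  tab$path <- paste(tab$from, "->", tab$to)
  out <- data.frame(path = tab$path, estimate = round(tab$estimate, 3),
                    se = round(tab$se, 3), cr = round(tab$cr, 3),
                    p = signif(tab$p_value, 3))
  print(out, row.names = FALSE)
  invisible(x)
}

as_edge_table <- function(fit) {
  if (inherits(fit, "path_fit")) {
    return(list(edges = fit$edges, diagram = fit$diagram))
  }
  if (is.data.frame(fit) &&
      all(c("from", "to", "estimate") %in% names(fit))) {
    return(list(edges = fit, diagram = path_diagram(fit[c("from", "to")])))
  }
  abort("expected a path_fit or a data.frame with from/to/estimate")
}

#' Decompose standardized effects into direct, indirect and total
#'
#' With B the matrix of direct standardized coefficients over the acyclic
#' diagram, the total-effect matrix is `(I - B)^-1 - I` and indirect effects
#' are total minus direct (equivalently, the sum over all directed paths of
#' length >= 2 of edge-coefficient products).
#'
#' @param fit a [fit_path_model()] result, or a data.frame with columns
#'   `from`, `to`, `estimate` (e.g. published coefficients).
#' @param diagram optional [path_diagram()]; defaults to the fit's diagram.
#' @return object of class `effect_table`: data.frame of construct pairs with
#'   direct, indirect, total (full precision) and *_3dp rounded companions.
#' @export
decompose_effects <- function(fit, diagram = NULL) {
  et <- as_edge_table(fit)
  if (is.null(diagram)) diagram <- et$diagram
  nodes <- diagram$nodes
  B <- edge_matrix(et$edges, nodes)
  I <- diag(length(nodes))
  Tm <- tryCatch(solve(I - B) - I,
                 error = function(e) abort("(I - B) is singular"))
  indirect <- Tm - B
  pairs <- which(Tm != 0 | B != 0, arr.ind = TRUE)
  tab <- data.frame(from = nodes[pairs[, 2]], to = nodes[pairs[, 1]],
                    direct = B[pairs], indirect = indirect[pairs],
                    total = Tm[pairs], stringsAsFactors = FALSE)
  ord <- order(match(tab$from, nodes), match(tab$to, nodes))
  tab <- tab[ord, , drop = FALSE]
  tab$direct_3dp <- round_half_up(tab$direct, 3)
  tab$indirect_3dp <- round_half_up(tab$indirect, 3)
  tab$total_3dp <- round_half_up(tab$total, 3)
  rownames(tab) <- NULL
  structure(tab, class = c("effect_table", "data.frame"),
            B = B, total_matrix = Tm)
}

#' @export
print.effect_table <- function(x, ...) {
  out <- data.frame(path = paste(x$from, "->", x$to),
                    direct = x$direct_3dp, indirect = x$indirect_3dp,
                    total = x$total_3dp)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Model-implied covariance of the constructs
#'
#' `Sigma = (I - B)^-1 Psi (I - B)^-T` with Psi the diagonal matrix of
#' exogenous variances and endogenous residual variances.
#'
#' @param fit a [fit_path_model()] result, or a data.frame with
#'   `from`/`to`/`estimate` plus a named `psi` vector supplied separately.
#' @param diagram optional diagram override.
#' @param psi named residual/exogenous variances (defaults to the fit's).
#' @return implied covariance matrix over the diagram's nodes.
#' @export
implied_covariance <- function(fit, diagram = NULL, psi = NULL) {
  et <- as_edge_table(fit)
  if (is.null(diagram)) diagram <- et$diagram
  if (is.null(psi)) {
    if (!inherits(fit, "path_fit")) {
      abort("psi must be supplied when fit is a bare edge table")
    }
    psi <- fit$psi
  }
  nodes <- diagram$nodes
  if (!all(nodes %in% names(psi))) abort("psi must cover every node")
  B <- edge_matrix(et$edges, nodes)
  A <- solve(diag(length(nodes)) - B)
  Sigma <- A %*% diag(psi[nodes], length(nodes)) %*% t(A)
  dimnames(Sigma) <- list(nodes, nodes)
  Sigma
}

#' Two-level significance stars
#'
#' Maps p-values to the reporting convention `*` p < 0.05, `**` p < 0.001.
#'
#' @param fit a `path_fit` (or any data.frame with a `p_value` column).
#' @return the edge table with a `stars` column.
#' @export
significance_report <- function(fit) {
  edges <- if (inherits(fit, "path_fit")) fit$edges else fit
  if (!"p_value" %in% names(edges)) abort("no p_value column")
  edges$stars <- ifelse(edges$p_value < 0.001, "**",
                        ifelse(edges$p_value < 0.05, "*", ""))
  edges
}
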