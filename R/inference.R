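#' Distance I-spline of one simulated (or observed) community
#'
#' Fits a distance-only generalised dissimilarity model to a community's
#' Bray-Curtis matrix and evaluates the fitted monotone distance transform
#' on a shared distance grid, so that splines from different runs are
#' directly comparable.
#'
#' @param community a [community_matrix()].
#' @param eval_grid distances (m) at which to evaluate the spline.
#' @param ... passed to [fit_gdm()].
#' @return numeric vector of spline values on `eval_grid`.
#' @export
community_spline <- function(community, eval_grid, ...) {
  d <- bray_curtis(community)
  pairs <- build_site_pairs(d)
  fit <- fit_gdm(pairs, "distance", ...)
  gdm_spline(fit, "distance", at = eval_grid)$y
}

#' Sweep a dispersal/speciation parameter grid through the simulator
#'
#' For every row of the parameter grid, runs a neutral coalescent census,
#' grids it into a community, fits a distance-only dissimilarity model and
#' exports its I-spline on a common evaluation grid. Each run gets a
#' deterministic seed derived from the master seed and its grid index, so
#' the sweep is reproducible and order-independent; per-run failures are
#' recorded and the sweep continues.
#'
#' @param par_grid data.frame with columns `sigma`, `tau`, `nu`.
#' @param landscape a [gen_landscape()] arena.
#' @param sample sample map passed to [sim_config()].
#' @param mode,m simulation mode and mixing penalty (see [sim_config()]).
#' @param seed master seed.
#' @param eval_grid distance grid; default 100 points from 0 to the
#'   maximum pairwise distance among sampled cells.
#' @param ... passed to [fit_gdm()].
#' @return object of class `spline_sweep`: `params` (the grid plus per-run
#'   seeds), `splines` (runs x grid-points matrix, NA rows on failure),
#'   `eval_grid`, `errors`.
#' @export
sweep_splines <- function(par_grid, landscape, sample = NULL,
                          mode = "naive", m = 1, seed = 1,
                          eval_grid = NULL, ...) {
  stopifnot(all(c("sigma", "tau", "nu") %in% names(par_grid)),
            nrow(par_grid) >= 1)
  if (is.null(eval_grid)) {
    cfg0 <- sim_config(landscape, nu = 1, dispersal_kernel(1, 1),
                       sample = sample, mode = "naive")
    cc <- cfg0$sample
    cs <- landscape$cell_size
    xy <- cbind((cc$col - 0.5) * cs, (cc$row - 0.5) * cs)
    eval_grid <- seq(0, max(stats::dist(xy)), length.out = 100)
  }
  seeds <- vapply(seq_len(nrow(par_grid)), function(i) child_seed(seed, i),
                  integer(1))
  splines <- matrix(NA_real_, nrow(par_grid), length(eval_grid))
  errors <- rep(NA_character_, nrow(par_grid))
  for (i in seq_len(nrow(par_grid))) {
    res <- tryCatch({
      cfg <- sim_config(landscape, nu = par_grid$nu[i],
                        dispersal_kernel(par_grid$sigma[i], par_grid$tau[i]),
                        m = m, mode = mode, sample = sample,
                        seed = seeds[i])
      comm <- census_to_community(coalescent_census(cfg))
      community_spline(comm, eval_grid, ...)
    }, error = function(e) e)
    if (inherits(res, "error")) errors[i] <- conditionMessage(res)
    else splines[i, ] <- res
  }
  params <- cbind(par_grid, seed = seeds)
  structure(list(params = params, splines = splines,
                 eval_grid = eval_grid, errors = errors),
            class = "spline_sweep")
}

#' Match a target I-spline against sweep candidates
#'
#' Scores every candidate spline against the target (root-mean-square
#' difference over the shared evaluation grid by default) and selects the
#' minimum; exact ties are broken towards smaller `nu`, then smaller
#' `sigma`, then smaller `tau`.
#'
#' @param target numeric vector on the sweep's evaluation grid.
#' @param sweep a [sweep_splines()] result (or a list with `params` and
#'   `splines`).
#' @param metric `"rmse"` or `"max"` (maximum absolute difference).
#' @return object of class `spline_match`: `scores`, `best` (parameter
#'   row), `best_index`.
#' @export
match_splines <- function(target, sweep, metric = c("rmse", "max")) {
  metric <- match.arg(metric)
  ok <- which(!is.na(sweep$splines[, 1]))
  if (!length(ok)) stop("no valid candidate splines to match against")
  diffs <- sweep$splines[ok, , drop = FALSE] -
    matrix(target, length(ok), length(target), byrow = TRUE)
  sc <- if (metric == "rmse") sqrt(rowMeans(diffs^2)) else
    apply(abs(diffs), 1, max)
  scores <- rep(NA_real_, nrow(sweep$splines))
  scores[ok] <- sc
  p <- sweep$params
  ord <- order(scores, p$nu, p$sigma, p$tau, na.last = TRUE)
  best <- ord[1]
  structure(list(scores = scores, best = p[best, , drop = FALSE],
                 best_index = best, metric = metric),
            class = "spline_match")
}

#' @export
print.spline_match <- function(x, ...) {
  cat("<spline_match> best candidate (", x$metric, " = ",
      format(x$scores[x$best_index], digits = 4), "):\n", sep = "")
  print(x$best)
  invisible(x)
}

#' Cross-forest-type consistency of the best-matching parameters
#'
#' The diagnostic for niche-independent dispersal: given one target spline
#' per forest type and a set of candidate parameter sets (each providing
#' either a single landscape-wide spline, or one spline per type), reports
#' whether a single candidate matches all types simultaneously -- i.e.
#' whether some candidate's score stays within `tol_factor` times the
#' per-type best score for every type at once.
#'
#' @param targets named list of target splines (one per forest type), all
#'   on the same evaluation grid.
#' @param candidates list with `params` (data.frame) and `splines`: either
#'   a runs x grid matrix (one landscape-wide spline per candidate) or a
#'   list of per-candidate matrices with one row per forest type.
#' @param tol_factor score tolerance relative to the per-type best
#'   (default 1.25).
#' @param metric passed to the scoring (`"rmse"` or `"max"`).
#' @return object of class `consistency_report`: per-type score matrix,
#'   per-type best candidate and score, the consistent candidate index (NA
#'   if none) and the logical `consistent`.
#' @export
consistency_test <- function(targets, candidates, tol_factor = 1.25,
                             metric = c("rmse", "max")) {
  metric <- match.arg(metric)
  stopifnot(length(targets) >= 1)
  n_cand <- nrow(candidates$params)
  score1 <- function(spl, target) {
    if (metric == "rmse") sqrt(mean((spl - target)^2)) else
      max(abs(spl - target))
  }
  scores <- matrix(NA_real_, n_cand, length(targets),
                   dimnames = list(NULL, names(targets)))
  for (ci in seq_len(n_cand)) {
    for (ti in seq_along(targets)) {
      spl <- if (is.list(candidates$splines))
        candidates$splines[[ci]][ti, ] else candidates$splines[ci, ]
      if (!anyNA(spl)) scores[ci, ti] <- score1(spl, targets[[ti]])
    }
  }
  best_score <- apply(scores, 2, min, na.rm = TRUE)
  best_cand <- apply(scores, 2, which.min)
  within <- sweep(scores, 2, tol_factor * best_score, `<=`)
  all_types <- which(rowSums(within, na.rm = TRUE) == length(targets) &
                       rowSums(!is.na(scores)) == length(targets))
  structure(list(scores = scores, best_score = best_score,
                 best_candidate = best_cand,
                 consistent = length(all_types) > 0,
                 consistent_candidates = all_types,
                 tol_factor = tol_factor, params = candidates$params),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat("<consistency_report> ", ncol(x$scores), " target(s), ",
      nrow(x$scores), " candidate(s): ",
      if (x$consistent) "CONSISTENT" else "NOT consistent",
      " (tolerance ", x$tol_factor, "x per-type best)\n", sep = "")
  invisible(x)
}
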