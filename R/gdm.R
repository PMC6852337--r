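#' Build a site-pair table for dissimilarity modelling
#'
#' Expands a dissimilarity matrix and a site-level environment table into
#' one row per unordered site pair, carrying the observed dissimilarity,
#' the Euclidean geographic distance between cell centres and the predictor
#' values at both sites. A `forest_type` factor, when present, is encoded
#' as orthogonal (Helmert) contrasts, giving `n_types - 1` numeric
#' predictors (`ft_c1`, `ft_c2`, ...).
#'
#' @param d dissimilarity matrix (e.g. [bray_curtis()]).
#' @param env data.frame of site-level predictors, rows matching `d`;
#'   numeric columns are used as-is, a `forest_type` factor becomes
#'   contrast columns. `x`/`y`/`cell` columns are ignored as predictors.
#' @param coords n x 2 site coordinates (m); defaults to
#'   `attr(d, "coords")` or the `x`/`y` columns of `env`.
#' @return object of class `site_pairs`: data.frame with `site1`, `site2`,
#'   `d`, `distance` and `x1_*`/`x2_*` predictor columns; the site-level
#'   table and coordinates are kept as attributes.
#' @export
build_site_pairs <- function(d, env = NULL, coords = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  coords <- coords %||% attr(d, "coords") %||%
    (if (!is.null(env) && all(c("x", "y") %in% names(env)))
      cbind(env$x, env$y))
  if (is.null(coords)) stop("site coordinates are required")
  coords <- as.matrix(coords)
  if (nrow(coords) != n) stop("coordinate rows do not match the sites of d")
  if (!is.null(env) && nrow(env) != n)
    stop("environment rows do not match the sites of d")

  site_env <- NULL
  if (!is.null(env)) {
    keep <- setdiff(names(env), c("x", "y", "cell"))
    site_env <- data.frame(row.names = seq_len(n))
    for (v in keep) {
      col <- env[[v]]
      if (is.factor(col) || is.character(col)) {
        f <- factor(col)
        if (nlevels(f) < 2) next
        C <- stats::contr.helmert(nlevels(f))
        for (j in seq_len(ncol(C)))
          site_env[[paste0(if (v == "forest_type") "ft" else v, "_c", j)]] <-
            C[as.integer(f), j]
      } else if (is.numeric(col)) {
        site_env[[v]] <- col
      }
    }
  }

  ij <- which(upper.tri(d), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  out <- data.frame(site1 = i, site2 = j, d = d[ij],
                    distance = sqrt((coords[i, 1] - coords[j, 1])^2 +
                                      (coords[i, 2] - coords[j, 2])^2))
  if (!is.null(site_env))
    for (v in names(site_env)) {
      out[[paste0("x1_", v)]] <- site_env[[v]][i]
      out[[paste0("x2_", v)]] <- site_env[[v]][j]
    }
  structure(out, class = c("site_pairs", "data.frame"),
            env = site_env, coords = coords,
            vars = c("distance", names(site_env)))
}

# Design matrix of I-spline terms for the requested predictors. For the
# geographic term the splines are evaluated at the pair distance itself;
# for environmental predictors each column is |I(x2) - I(x1)|, which under
# non-negative coefficients equals the difference of the fitted monotone
# transforms. Returns the matrix plus per-predictor knots/column maps.
gdm_design <- function(pairs, predictors, knots = NULL, n_splines = 3,
                       order = 2) {
  X <- NULL; kn <- list(); cols <- list(); dropped <- character()
  for (v in predictors) {
    if (v == "distance") {
      vals <- pairs$distance
      kv <- knots[[v]] %||% gdm_knots(vals, n_splines)
      if (is.null(kv)) { dropped <- c(dropped, v); next }
      M <- ispline_basis(vals, kv, order)
    } else {
      x1 <- pairs[[paste0("x1_", v)]]; x2 <- pairs[[paste0("x2_", v)]]
      if (is.null(x1)) stop("predictor not found in pair table: ", v)
      kv <- knots[[v]] %||% gdm_knots(c(x1, x2), n_splines)
      if (is.null(kv)) { dropped <- c(dropped, v); next }
      M <- abs(ispline_basis(x2, kv, order) - ispline_basis(x1, kv, order))
    }
    colnames(M) <- paste0(v, "_s", seq_len(ncol(M)))
    cols[[v]] <- ncol(X %||% matrix(0, nrow(pairs), 0)) + seq_len(ncol(M))
    X <- cbind(X, M)
    kn[[v]] <- kv
  }
  list(X = X, knots = kn, cols = cols, dropped = dropped)
}

# Binomial-type deviance used throughout the GDM fits.
gdm_deviance <- function(y, mu) {
  mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- ifelse(y < 1, (1 - y) * log((1 - y) / (1 - mu)), 0)
  2 * sum(t1 + t2)
}

#' Fit a generalised dissimilarity model
#'
#' Regresses pairwise dissimilarity on monotone I-spline transforms of
#' geographic distance and environmental differences under the
#' negative-exponential link: predicted dissimilarity is
#' `1 - exp(-eta)` with `eta = a0 + sum_k |f_k(x_2k) - f_k(x_1k)|`, each
#' `f_k` a non-negative combination of I-splines (geographic distance
#' enters through a single monotone spline of the pair distance).
#' Coefficients (and the intercept) are constrained non-negative and
#' estimated by iteratively reweighted non-negative least squares on the
#' binomial-type deviance, with step halving whenever an update fails to
#' decrease the deviance. Observed dissimilarities of 1 are truncated to
#' `1 - 1e-9` so the objective stays finite.
#'
#' @param pairs a [build_site_pairs()] table.
#' @param predictors character vector of predictor names (`"distance"`
#'   and/or environment columns); default: every available predictor.
#' @param n_splines I-splines per predictor (knots at evenly spaced
#'   percentiles; default 3 = 0/50/100th).
#' @param order M-spline order of the basis (default 2, quadratic
#'   I-splines).
#' @param knots optional named list of explicit knot vectors.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   coefficient change.
#' @return object of class `gdm_fit`: intercept, per-predictor coefficients
#'   and knots, null and residual deviance, percent deviance explained
#'   (`explained`, clamped to `[0, 100]`; `explained_raw` unclamped),
#'   convergence diagnostics.
#' @export
fit_gdm <- function(pairs, predictors = NULL, n_splines = 3, order = 2,
                    knots = NULL, max_iter = 200, tol = 1e-8) {
  predictors <- predictors %||% attr(pairs, "vars") %||% "distance"
  if (nrow(pairs) < 10) stop("need at least 10 site pairs")
  y <- pmin(pmax(pairs$d, 0), 1 - 1e-9)

  des <- gdm_design(pairs, predictors, knots, n_splines, order)
  for (v in des$dropped)
    warning("dropping degenerate (constant) predictor: ", v)
  X <- cbind(`(Intercept)` = 1, des$X)
  p <- ncol(X)

  mu0 <- mean(y)
  dev_null <- gdm_deviance(y, rep(mu0, length(y)))

  beta <- c(max(-log(1 - mu0), 0), rep(0, p - 1))
  dev_old <- gdm_deviance(y, 1 - exp(-drop(X %*% beta)))
  converged <- FALSE; it <- 0
  while (it < max_iter) {
    it <- it + 1
    eta <- pmin(drop(X %*% beta), 30)
    mu <- pmin(pmax(1 - exp(-eta), 1e-10), 1 - 1e-10)
    w <- pmin((1 - mu) / mu, 1e8)
    z <- eta + (y - mu) / (1 - mu)
    sw <- sqrt(w)
    sol <- pracma::lsqnonneg(X * sw, z * sw)$x
    # step-halve towards the previous iterate if the deviance worsens
    h <- 0
    repeat {
      dev_new <- gdm_deviance(y, 1 - exp(-pmin(drop(X %*% sol), 30)))
      if (dev_new <= dev_old + 1e-12 || h >= 25) break
      sol <- (sol + beta) / 2
      h <- h + 1
    }
    delta <- max(abs(sol - beta))
    beta <- sol; dev_old <- dev_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GDM IRLS did not converge in ", max_iter,
            " iterations (last coefficient change ",
            format(delta, digits = 3), ")")

  coefs <- lapply(des$cols, function(ix) unname(beta[-1][ix]))
  explained_raw <- 100 * (1 - dev_old / dev_null)
  structure(list(intercept = beta[1], coefficients = coefs,
                 knots = des$knots, predictors = names(des$cols),
                 order = order, n_splines = n_splines,
                 deviance = dev_old, null_deviance = dev_null,
                 explained = min(max(explained_raw, 0), 100),
                 explained_raw = explained_raw,
                 converged = converged, iterations = it,
                 n_pairs = nrow(pairs)),
            class = "gdm_fit")
}

#' @export
print.gdm_fit <- function(x, ...) {
  cat("<gdm_fit> ", length(x$predictors), " predictor(s): ",
      paste(x$predictors, collapse = ", "), "\n", sep = "")
  cat("  deviance explained: ", format(x$explained, digits = 4),
      "% (", x$n_pairs, " pairs, ", x$iterations, " IRLS iterations",
      if (!x$converged) ", NOT converged", ")\n", sep = "")
  invisible(x)
}

#' Predict pair dissimilarities from a fitted GDM
#'
#' @param object a [fit_gdm()] model.
#' @param pairs a [build_site_pairs()] table with the model's predictors.
#' @param ... unused.
#' @return numeric vector of predicted dissimilarities in `[0, 1)`.
#' @export
predict.gdm_fit <- function(object, pairs, ...) {
  des <- gdm_design(pairs, object$predictors, knots = object$knots,
                    n_splines = object$n_splines, order = object$order)
  eta <- object$intercept +
    drop(des$X %*% unlist(object$coefficients[object$predictors]))
  1 - exp(-eta)
}

#' Evaluate a fitted monotone transform (I-spline) of one predictor
#'
#' The fitted `f(x) = sum_s beta_s I_s(x)` for a single predictor: its
#' slope is the rate of compositional turnover along the predictor and its
#' maximum (the sum of the coefficients, reached at the upper knot) the
#' total turnover the predictor accounts for.
#'
#' @param model a [fit_gdm()] model.
#' @param predictor predictor name (default `"distance"`).
#' @param at evaluation points; default a 100-point grid over the knot
#'   range.
#' @param n grid size when `at` is missing.
#' @return data.frame with columns `x` and `y`.
#' @export
gdm_spline <- function(model, predictor = "distance", at = NULL, n = 100) {
  if (!predictor %in% model$predictors)
    stop("predictor not in model: ", predictor)
  kv <- model$knots[[predictor]]
  at <- at %||% seq(kv[1], kv[length(kv)], length.out = n)
  y <- drop(ispline_basis(at, kv, model$order) %*%
              model$coefficients[[predictor]])
  data.frame(x = at, y = y)
}

#' Serialise a fitted GDM to JSON
#'
#' Writes (or returns) the model's knots, coefficients, intercept and
#' deviance summary in a plain JSON form that round-trips through
#' [jsonlite::read_json()].
#'
#' @param model a [fit_gdm()] model.
#' @param path optional file path; when `NULL` the JSON string is
#'   returned.
#' @return the path (invisibly) or a JSON string.
#' @export
gdm_to_json <- function(model, path = NULL) {
  payload <- list(intercept = model$intercept,
                  predictors = model$predictors,
                  knots = model$knots,
                  coefficients = model$coefficients,
                  order = model$order, n_splines = model$n_splines,
                  deviance = model$deviance,
                  null_deviance = model$null_deviance,
                  explained = model$explained, n_pairs = model$n_pairs)
  if (is.null(path))
    return(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Partition dissimilarity deviance into distance, environment and overlap
#'
#' Fits distance-only, environment-only and full models and splits the full
#' model's percent deviance explained into the share unique to geographic
#' distance (D = full - explained(E)), unique to the environment
#' (E = full - explained(D)) and their spatially autocorrelated overlap
#' (DxE = explained(D) + explained(E) - full). A negative component
#' (possible when the separate fits overlap more than they add) is clamped
#' to zero and the remaining components rescaled so the three still sum to
#' the full model's explained deviance. Two distance splines are exported:
#' the distance transform of the full model (`spline_d_only`, the pattern
#' without environment-covarying variation) and of the distance-only model
#' (`spline_d_plus_dxe`, the observed pattern).
#'
#' @param pairs a [build_site_pairs()] table.
#' @param env_predictors environmental predictor names (default: all
#'   non-distance predictors in `pairs`).
#' @param ... passed to [fit_gdm()].
#' @return object of class `gdm_partition`: percentages `D`, `E`, `DxE`,
#'   `unexplained`, `full`, the three fitted models and the exported
#'   splines.
#' @export
gdm_partition <- function(pairs, env_predictors = NULL, ...) {
  env_predictors <- env_predictors %||%
    setdiff(attr(pairs, "vars"), "distance")
  if (!length(env_predictors)) stop("no environmental predictors available")
  m_d <- fit_gdm(pairs, "distance", ...)
  m_e <- fit_gdm(pairs, env_predictors, ...)
  m_full <- fit_gdm(pairs, c("distance", env_predictors), ...)

  full <- m_full$explained
  uD <- full - m_e$explained
  uE <- full - m_d$explained
  shared <- m_d$explained + m_e$explained - full
  parts <- c(D = uD, E = uE, DxE = shared)
  if (any(parts < 0)) {
    parts[parts < 0] <- 0
    s <- sum(parts)
    if (s > 0) parts <- parts * full / s else parts[] <- full / 3
  }
  structure(list(D = unname(parts["D"]), E = unname(parts["E"]),
                 DxE = unname(parts["DxE"]),
                 unexplained = 100 - full, full = full,
                 models = list(distance = m_d, environment = m_e,
                               full = m_full),
                 spline_d_only = gdm_spline(m_full, "distance"),
                 spline_d_plus_dxe = gdm_spline(m_d, "distance")),
            class = "gdm_partition")
}

#' @export
print.gdm_partition <- function(x, ...) {
  cat("GDM deviance partition (% of dissimilarity deviance):\n")
  cat(sprintf("  D (distance only)      %6.2f%%\n", x$D))
  cat(sprintf("  E (environment only)   %6.2f%%\n", x$E))
  cat(sprintf("  DxE (shared)           %6.2f%%\n", x$DxE))
  cat(sprintf("  total explained        %6.2f%%\n", x$full))
  invisible(x)
}

#' Permutation importance of environmental predictors
#'
#' Randomises the site-level values of each environmental predictor in
#' turn (consistently across all pairs containing the site), refits the
#' model, and reports the mean loss in percent deviance explained over
#' `n_perm` permutations.
#'
#' @param model a [fit_gdm()] model.
#' @param pairs the [build_site_pairs()] table the model was fitted to.
#' @param n_perm permutations per predictor (default 50).
#' @param seed integer seed.
#' @return named numeric vector of mean explained-deviance losses (percent
#'   points), one per environmental predictor in the model.
#' @export
gdm_importance <- function(model, pairs, n_perm = 50, seed = NULL) {
  env <- attr(pairs, "env")
  vars <- intersect(model$predictors, names(env))
  if (!length(vars)) return(setNames(numeric(0), character(0)))
  i1 <- pairs$site1; i2 <- pairs$site2
  with_seed(seed, {
    out <- vapply(vars, function(v) {
      losses <- vapply(seq_len(n_perm), function(b) {
        perm <- sample.int(nrow(env))
        p2 <- pairs
        p2[[paste0("x1_", v)]] <- env[[v]][perm][i1]
        p2[[paste0("x2_", v)]] <- env[[v]][perm][i2]
        m2 <- suppressWarnings(
          fit_gdm(p2, model$predictors, n_splines = model$n_splines,
                  order = model$order))
        model$explained - m2$explained
      }, numeric(1))
      mean(losses)
    }, numeric(1))
    setNames(out, vars)
  })
}
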