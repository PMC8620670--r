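# Richness-maintaining null model and the nearest taxon index (NTI).

#' Draw one null assemblage from the reference pool
#'
#' Uniform sample without replacement of `richness` species names from the
#' reference pool (here, typically the full alien species list). Uses R's
#' global RNG; seed upstream for reproducibility.
#'
#' @param pool character vector of species names.
#' @param richness number of names to draw, `2 <= richness <= length(pool)`.
#' @return Character vector of `richness` names.
#' @export
sample_null_assemblage <- function(pool, richness) {
  if (richness < 2L) stop("richness must be at least 2", call. = FALSE)
  if (richness > length(pool))
    stop(sprintf("richness (%d) exceeds pool size (%d)", richness, length(pool)),
         call. = FALSE)
  pool[sample.int(length(pool), richness)]
}

#' Nearest taxon index of an assemblage
#'
#' Standardized effect size of MNTD against a null of equally rich
#' assemblages drawn uniformly (without replacement) from a reference pool:
#' `NTI = -(MNTD_obs - mean(MNTD_null)) / sd(MNTD_null)`, with the sample
#' (n-1) standard deviation. Positive NTI means the assemblage is more
#' closely related than random draws — phylogenetic clustering; negative
#' means overdispersion; zero means indistinguishable from random.
#'
#' The null is enumerated exhaustively when the number of distinct subsets
#' `choose(|pool|, richness)` is at most `exhaustive_limit`; otherwise
#' `n_draws` Monte-Carlo draws are taken. A constant null (sd = 0, e.g. when
#' the assemblage *is* the pool, so every richness-preserving draw
#' reproduces it) leaves NTI undefined: it is reported as `NA` with
#' `degenerate = TRUE`, never as 0 or infinity. Setting
#' `degenerate = "bootstrap"` instead draws the null *with* replacement,
#' which keeps the SES defined for the pool-vs-pool comparison.
#'
#' @param dm patristic matrix from [patristic_matrix()].
#' @param assemblage character vector of >= 2 tip labels, subset of `pool`.
#' @param pool reference pool of tip labels (subset of `rownames(dm)`).
#' @param n_draws number of Monte-Carlo null draws (default 1000).
#' @param seed optional integer seed for the draws.
#' @param mode `"auto"` (default), `"monte_carlo"` or `"exhaustive"`.
#' @param degenerate `"flag"` (default: NA + diagnostic) or `"bootstrap"`
#'   (resample with replacement when the without-replacement null is
#'   constant because assemblage = pool).
#' @param assemblage_name label carried into the result.
#' @param exhaustive_limit max subset count for exhaustive enumeration.
#' @return An `nti_result`: list with `assemblage_name`, `richness`,
#'   `mntd_observed`, `null_mean`, `null_sd`, `nti`, `n_draws`, `mode`,
#'   `seed`, `degenerate`.
#' @export
nti <- function(dm, assemblage, pool, n_draws = 1000L, seed = NULL,
                mode = c("auto", "monte_carlo", "exhaustive"),
                degenerate = c("flag", "bootstrap"),
                assemblage_name = "assemblage", exhaustive_limit = 10000) {
  mode <- match.arg(mode)
  degenerate <- match.arg(degenerate)
  validate_dm(dm)
  assemblage <- unique(assemblage)
  pool <- unique(pool)
  if (length(assemblage) < 2L)
    stop("NTI needs an assemblage of at least 2 taxa", call. = FALSE)
  if (!all(assemblage %in% pool))
    stop("assemblage must be a subset of the reference pool", call. = FALSE)
  pool_idx <- match_labels(dm, pool, "pool")
  obs_idx <- match_labels(dm, assemblage)
  k <- length(obs_idx)
  if (n_draws < 1L) stop("n_draws must be at least 1", call. = FALSE)

  n_subsets <- choose(length(pool_idx), k)
  if (mode == "auto")
    mode <- if (n_subsets <= exhaustive_limit) "exhaustive" else "monte_carlo"
  if (mode == "exhaustive" && n_subsets > exhaustive_limit)
    stop(sprintf("exhaustive null needs %.0f subsets (> limit %d)",
                 n_subsets, exhaustive_limit), call. = FALSE)

  mntd_obs <- cpp_mntd(dm, obs_idx)
  boot <- degenerate == "bootstrap" && setequal(assemblage, pool)

  if (!is.null(seed)) set.seed(seed)
  if (boot) {
    draws <- vapply(seq_len(n_draws),
                    function(i) sort(sample(pool_idx, k, replace = TRUE)),
                    integer(k))
    mode <- "monte_carlo"
  } else if (mode == "exhaustive") {
    draws <- utils::combn(pool_idx, k)
  } else {
    draws <- vapply(seq_len(n_draws),
                    function(i) sample(pool_idx, k),
                    integer(k))
  }
  null_mntd <- cpp_null_mntd(dm, draws)

  null_mean <- mean(null_mntd)
  null_sd <- stats::sd(null_mntd)
  degen <- !is.finite(null_sd) || null_sd == 0
  value <- if (degen) NA_real_ else -(mntd_obs - null_mean) / null_sd
  if (degen)
    message(sprintf(
      "NTI undefined for '%s': constant null distribution (sd = 0%s)",
      assemblage_name,
      if (setequal(assemblage, pool)) "; assemblage equals the reference pool" else ""))

  structure(list(assemblage_name = assemblage_name,
                 richness = k,
                 mntd_observed = mntd_obs,
                 null_mean = null_mean,
                 null_sd = if (is.finite(null_sd)) null_sd else NA_real_,
                 nti = value,
                 n_draws = ncol(draws),
                 mode = mode,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 degenerate = degen),
            class = "nti_result")
}

#' @export
print.nti_result <- function(x, ...) {
  cat(sprintf("NTI for '%s' (richness %d, %s null, %d draws)\n",
              x$assemblage_name, x$richness, x$mode, x$n_draws))
  cat(sprintf("  MNTD observed %.4f | null mean %.4f sd %.4f\n",
              x$mntd_observed, x$null_mean, x$null_sd))
  if (x$degenerate) {
    cat("  NTI undefined: constant null distribution\n")
  } else {
    verdict <- if (x$nti > 0) "clustered" else if (x$nti < 0) "overdispersed" else "random"
    cat(sprintf("  NTI = %.4f (%s)\n", x$nti, verdict))
  }
  invisible(x)
}

#' NTI for all five invasion-stage assemblages
#'
#' Computes NTI for `alien`, `casual`, `naturalized`, `nni` and `invasive`
#' against the *same* reference pool — by default the alien set, i.e. all
#' species on the checklist that are on the tree. Each assemblage gets an
#' independent sub-seed derived as `seed + index - 1` in the fixed
#' assemblage order, so adding or reordering assemblages never shifts
#' another's draws. Note the alien assemblage equals the pool, so its
#' without-replacement null is degenerate (see [nti()]).
#'
#' @param dm patristic matrix.
#' @param assemblages an `assemblage_set` from [derive_assemblages()] (or a
#'   named list of species-name vectors with those five names).
#' @param n_draws,seed,degenerate,exhaustive_limit passed to [nti()].
#' @param pool reference pool; default `assemblages$alien`.
#' @return List of `nti_result`, class `nti_set`; see
#'   [as.data.frame.nti_set()].
#' @export
nti_all <- function(dm, assemblages, n_draws = 1000L, seed = NULL,
                    pool = NULL, degenerate = c("flag", "bootstrap"),
                    exhaustive_limit = 10000) {
  degenerate <- match.arg(degenerate)
  stopifnot(all(assemblage_names %in% names(assemblages)))
  if (is.null(pool)) pool <- assemblages[["alien"]]
  res <- lapply(seq_along(assemblage_names), function(i) {
    nm <- assemblage_names[i]
    nti(dm, assemblages[[nm]], pool, n_draws = n_draws,
        seed = if (is.null(seed)) NULL else seed + i - 1L,
        degenerate = degenerate, assemblage_name = nm,
        exhaustive_limit = exhaustive_limit)
  })
  names(res) <- assemblage_names
  structure(res, class = "nti_set")
}

#' Flatten NTI results to a data frame
#'
#' @param x an `nti_set` from [nti_all()].
#' @param ... unused.
#' @export
as.data.frame.nti_set <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), function(r)
    data.frame(assemblage = r$assemblage_name, richness = r$richness,
               mntd_observed = r$mntd_observed, null_mean = r$null_mean,
               null_sd = r$null_sd, nti = r$nti, n_draws = r$n_draws,
               mode = r$mode, seed = r$seed, degenerate = r$degenerate,
               stringsAsFactors = FALSE)))
}

#' @export
print.nti_set <- function(x, ...) {
  df <- as.data.frame(x)
  df$nti <- round(df$nti, 4)
  df$mntd_observed <- round(df$mntd_observed, 4)
  df$null_mean <- round(df$null_mean, 4)
  df$null_sd <- round(df$null_sd, 4)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
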