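# Small-world and scale-free verdicts.
#
# The criteria are qualitative in origin ("clustering far greater than the
# random counterpart, path length almost as small"); the thresholds that
# operationalise them here are conventions, exposed as arguments and echoed
# in the verdict objects.

#' Small-world test against a matched random-graph ensemble
#'
#' A network is classified small-world when its clustering coefficient is
#' at least `theta_C` times the ensemble mean of its G(N,M) counterpart
#' and its average path length is at most `theta_L` times the ensemble
#' mean.
#'
#' @param summary a `network_summary` of the observed network.
#' @param ensemble a `random_graph_ensemble` built with the same N and M.
#' @param theta_C minimum clustering ratio C_obs / C_rand (default 10).
#' @param theta_L maximum path-length ratio L_obs / L_rand (default 1.5).
#' @return list of class `small_world_verdict` with the observed and null
#'   values, both ratios, the thresholds and `is_small_world`.
#' @export
small_world_test <- function(summary, ensemble, theta_C = 10, theta_L = 1.5) {
  stopifnot(inherits(summary, "network_summary"),
            inherits(ensemble, "random_graph_ensemble"))
  if (summary$N != ensemble$N || summary$M != ensemble$M) {
    stop("ensemble size mismatch: network has N = ", summary$N, ", M = ",
         summary$M, " but ensemble was built with N = ", ensemble$N,
         ", M = ", ensemble$M)
  }
  c_ratio <- summary$C / ensemble$mean_C
  l_ratio <- summary$L / ensemble$mean_L
  structure(list(
    C_obs = summary$C, C_rand = ensemble$mean_C,
    L_obs = summary$L, L_rand = ensemble$mean_L,
    c_ratio = c_ratio, l_ratio = l_ratio,
    theta_C = theta_C, theta_L = theta_L,
    is_small_world = isTRUE(c_ratio >= theta_C && l_ratio <= theta_L)
  ), class = "small_world_verdict")
}

#' @export
print.small_world_verdict <- function(x, ...) {
  cat("<small_world_verdict> ", if (x$is_small_world) "SMALL-WORLD"
      else "not small-world", "\n",
      "  C: ", signif(x$C_obs, 4), " vs random ", signif(x$C_rand, 4),
      "  (ratio ", signif(x$c_ratio, 4), ", threshold >= ", x$theta_C, ")\n",
      "  L: ", signif(x$L_obs, 4), " vs random ", signif(x$L_rand, 4),
      "  (ratio ", signif(x$l_ratio, 4), ", threshold <= ", x$theta_L, ")\n",
      sep = "")
  invisible(x)
}

#' Scale-free test via the cumulative log-log power-law fit
#'
#' A network is classified scale-free when the log-log OLS fit to its
#' cumulative degree distribution ([fit_power_law_loglog()]) has
#' R^2 >= `r2_threshold`.
#'
#' @param dd a `degree_distribution`.
#' @param r2_threshold minimum R^2 (default 0.95).
#' @return list of class `scale_free_verdict` with `fit`, `r2_threshold`
#'   and `is_scale_free`.
#' @export
scale_free_test <- function(dd, r2_threshold = 0.95) {
  fit <- fit_power_law_loglog(dd)
  structure(list(fit = fit, r2_threshold = r2_threshold,
                 is_scale_free = isTRUE(fit$r2 >= r2_threshold)),
            class = "scale_free_verdict")
}

#' @export
print.scale_free_verdict <- function(x, ...) {
  cat("<scale_free_verdict> ", if (x$is_scale_free) "SCALE-FREE"
      else "not scale-free",
      ": slope = ", round(x$fit$slope, 3), ", R^2 = ", round(x$fit$r2, 4),
      " (threshold ", x$r2_threshold, ")\n", sep = "")
  invisible(x)
}
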