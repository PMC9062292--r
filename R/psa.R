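#' Build a random sampler for one parameter specification
#'
#' Method-of-moments construction around the base value with
#' `sd = (high - low) / (2 * 1.96)`: beta parameters matched to (mean, sd) on
#' \[0, 1\] for probabilities/utilities/disutilities, gamma shape/rate matched
#' to (mean, sd) for costs, and plain normal for anthropometrics. Hazard
#' ratios follow the published distribution label (`"normal"`); a log-normal
#' alternative (normal on the log scale with `sd = (log high - log low)/3.92`)
#' is available via the configuration switch `hr_psa_dist = "lognormal"`.
#' Draws that are invalid for the model (non-positive hazard ratios or
#' anthropometrics, progressive-disease utility above the progression-free
#' utility) are rejected and the parameter vector resampled jointly by
#' [run_psa()], never clamped. A zero-width range gives a point mass at the
#' base value.
#'
#' @param name Parameter name (used to pick the hazard-ratio treatment).
#' @param base Base value (distribution mean).
#' @param low,high Range limits (95% CI or +/-50% band).
#' @param dist `"beta"`, `"gamma"`, `"normal"` or `"fixed"`.
#' @param hr_dist Sampling scale for hazard ratios: `"normal"` or
#'   `"lognormal"`.
#' @return A function of `n` returning `n` draws.
#' @export
build_sampler <- function(name, base, low, high, dist, hr_dist = "normal") {
  if (dist == "fixed") stop("fixed parameters have no sampler", call. = FALSE)
  if (high < low) stop("invalid range: high < low", call. = FALSE)
  sd <- (high - low) / (2 * stats::qnorm(0.975))
  if (high == low) return(function(n) rep(base, n))
  is_hr <- grepl("^hr_", name)
  if (is_hr && hr_dist == "lognormal") {
    sdlog <- (log(high) - log(low)) / (2 * stats::qnorm(0.975))
    return(function(n) stats::rlnorm(n, meanlog = log(base), sdlog = sdlog))
  }
  switch(dist,
    beta = {
      if (base <= 0 || base >= 1) {
        stop("beta mean must lie strictly inside (0, 1)", call. = FALSE)
      }
      v <- sd^2
      a <- base * (base * (1 - base) / v - 1)
      b <- a * (1 - base) / base
      if (a <= 0 || b <= 0) {
        stop("beta method-of-moments failed (variance too large)", call. = FALSE)
      }
      function(n) stats::rbeta(n, a, b)
    },
    gamma = {
      if (base <= 0) stop("gamma mean must be positive", call. = FALSE)
      shape <- (base / sd)^2
      rate <- base / sd^2
      function(n) stats::rgamma(n, shape = shape, rate = rate)
    },
    normal = function(n) stats::rnorm(n, mean = base, sd = sd),
    stop("unknown distribution: ", dist, call. = FALSE))
}

psa_param_table <- function(config) {
  tab <- param_table()
  tab <- tab[tab$vary_psa, c("name", "base", "low", "high", "dist")]
  tab$base <- unlist(config$params[tab$name])
  tab
}

draw_valid <- function(samplers, params, max_attempts = 100) {
  for (attempt in seq_len(max_attempts)) {
    draw <- lapply(samplers, function(f) f(1))
    pos <- function(x) is.null(x) || x > 0
    below_upfs <- function(x) is.null(x) || is.null(draw$u_pfs) || x < draw$u_pfs
    ok <- pos(draw$hr_os) && pos(draw$hr_pfs) && pos(draw$weight) &&
      pos(draw$bsa) && pos(draw$crcl) &&
      below_upfs(draw$u_pd) && below_upfs(draw$du_combo) &&
      below_upfs(draw$du_chemo) &&
      (is.null(draw$u_pfs) || draw$u_pfs < 1)
    if (ok) return(list(draw = draw, attempts = attempt))
  }
  stop("no valid parameter draw after ", max_attempts, " attempts",
       call. = FALSE)
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation of joint parameter uncertainty: for each draw all
#' non-fixed parameters are sampled from their distributions (Weibull
#' parameters and the discount rate stay fixed), the full two-arm model is
#' evaluated and incremental results recorded. A master seed spawns
#' independent per-draw substreams so draws are order-independent and
#' reproducible. Invalid draws are rejected and resampled (up to 100 attempts
#' per draw); the total number of rejections is reported.
#'
#' @param config A [default_config()] object.
#' @param n_draws Number of Monte-Carlo draws (published analysis: 1000).
#' @param seed Master integer seed.
#' @param specs Parameter table (`name`, `base`, `low`, `high`, `dist`);
#'   defaults to the non-fixed published parameters with base values from
#'   `config`.
#' @return An object of class `psa_result`: data frame with `draw`, one
#'   column per sampled parameter, `cost_ref`, `qaly_ref`, `cost_comp`,
#'   `qaly_comp`, `delta_cost`, `delta_qalys`; the number of rejected draws
#'   and the WTP are attributes.
#' @export
run_psa <- function(config = default_config(), n_draws = 1000, seed = 1,
                    specs = psa_param_table(config)) {
  stopifnot(n_draws >= 1, is.numeric(seed))
  tab <- specs
  samplers <- stats::setNames(
    lapply(seq_len(nrow(tab)), function(i) {
      build_sampler(tab$name[i], tab$base[i], tab$low[i], tab$high[i],
                    tab$dist[i], hr_dist = config$hr_psa_dist)
    }), tab$name)
  rejections <- 0L
  rows <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    set.seed((as.integer(seed) %% 1000003L) * 2011L + i)  # per-draw substream
    dv <- draw_valid(samplers)
    rejections <- rejections + dv$attempts - 1L
    cfg <- config
    cfg$params[names(dv$draw)] <- dv$draw
    res <- run_base_case(cfg)
    rows[[i]] <- data.frame(
      draw = i, as.data.frame(dv$draw),
      cost_ref = res$reference$cost, qaly_ref = res$reference$qalys,
      cost_comp = res$comparator$cost, qaly_comp = res$comparator$qalys,
      delta_cost = res$incremental$delta_cost,
      delta_qalys = res$incremental$delta_qalys)
  }
  out <- do.call(rbind, rows)
  attr(out, "rejections") <- rejections
  attr(out, "wtp") <- config$wtp_per_qaly
  attr(out, "seed") <- seed
  class(out) <- c("psa_result", "data.frame")
  out
}

#' Probability of cost-effectiveness at a willingness-to-pay threshold
#'
#' Fraction of draws with non-negative net monetary benefit
#' (`wtp * delta_qalys - delta_cost >= 0`).
#'
#' @param psa A [run_psa()] result.
#' @param wtp Threshold(s) in US$/QALY.
#' @export
prob_cost_effective <- function(psa, wtp) {
  stopifnot(inherits(psa, "psa_result"))
  vapply(wtp, function(w) mean(w * psa$delta_qalys - psa$delta_cost >= 0),
         numeric(1))
}

#' Cost-effectiveness acceptability curve
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Vector of willingness-to-pay thresholds (US$/QALY).
#' @return Data frame with columns `wtp` and `prob_ce`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 150000, by = 2500)) {
  stopifnot(length(psa$delta_cost) > 0)
  data.frame(wtp = wtp_grid, prob_ce = prob_cost_effective(psa, wtp_grid))
}

#' Plot the cost-effectiveness acceptability curve
#'
#' @param ceac_df A [ceac()] data frame.
#' @param wtp Optional threshold marked with a vertical line.
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_df, wtp = NULL) {
  p <- ggplot2::ggplot(ceac_df, ggplot2::aes(x = .data$wtp, y = .data$prob_ce)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (US$/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) p <- p + ggplot2::geom_vline(xintercept = wtp, linetype = 2)
  p
}

#' Incremental cost-effectiveness plane scatter
#'
#' @param psa A [run_psa()] result.
#' @param wtp Threshold drawn as a line through the origin (defaults to the
#'   WTP the analysis was run with).
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, wtp = attr(psa, "wtp")) {
  ggplot2::ggplot(as.data.frame(psa),
                  ggplot2::aes(x = .data$delta_qalys, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8, colour = "steelblue") +
    ggplot2::geom_abline(slope = wtp, intercept = 0, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (US$)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}
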