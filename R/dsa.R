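#' Parameter specifications for the one-way sensitivity analysis
#'
#' One row per parameter varied in the deterministic sensitivity analysis:
#' hazard ratios, utilities, disutilities and discontinuation probabilities at
#' their 95% confidence limits, the discount rate over 0-8%, and all prices,
#' costs and anthropometrics at +/-50% of baseline. Weibull survival
#' parameters are excluded (fixed). The nivolumab price is carried for
#' completeness although the progressive-disease state is costed with the
#' aggregate subsequent-therapy cost, so its spread is zero.
#'
#' @param config A [default_config()] object (supplies current base values).
#' @return Data frame with columns `name`, `base`, `low`, `high`, `dist`.
#' @export
param_specs <- function(config = default_config()) {
  tab <- param_table()
  tab <- tab[tab$vary_dsa, c("name", "base", "low", "high", "dist")]
  tab$base <- unlist(config$params[tab$name])
  bad <- tab$low > tab$base | tab$high < tab$base
  if (any(bad)) {
    stop("DSA range does not bracket the base value for: ",
         paste(tab$name[bad], collapse = ", "), call. = FALSE)
  }
  rownames(tab) <- NULL
  tab
}

#' One-way deterministic sensitivity analysis
#'
#' Reruns the full two-arm model twice per parameter (once at the lower and
#' once at the upper limit, all other parameters at base) and records the
#' resulting ICERs, sorted by tornado spread. A model failure at an extreme is
#' recorded in the `error` column and the analysis continues.
#'
#' @param config A [default_config()] object.
#' @param specs Parameter specification table from [param_specs()].
#' @return An object of class `dsa_result`: a data frame with `name`, `base`,
#'   `low`, `high`, `icer_low`, `icer_high`, `nmb_low`, `nmb_high`, `spread`,
#'   `base_between` (whether the base ICER lies between the two extremes, NA
#'   when either extreme is dominated/undefined) and `error`, ordered by
#'   decreasing spread, with the base-case ICER and WTP as attributes.
#' @export
run_dsa <- function(config = default_config(), specs = param_specs(config)) {
  base_run <- run_base_case(config)
  base_icer <- base_run$incremental$icer
  one <- function(name, value) {
    cfg <- config
    cfg$params[[name]] <- value
    run_base_case(cfg)
  }
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    s <- specs[i, ]
    res <- tryCatch({
      lo <- one(s$name, s$low)
      hi <- one(s$name, s$high)
      data.frame(name = s$name, base = s$base, low = s$low, high = s$high,
                 icer_low = lo$incremental$icer, icer_high = hi$incremental$icer,
                 nmb_low = lo$nmb, nmb_high = hi$nmb,
                 spread = abs(hi$incremental$icer - lo$incremental$icer),
                 error = NA_character_)
    }, error = function(e) {
      data.frame(name = s$name, base = s$base, low = s$low, high = s$high,
                 icer_low = NA_real_, icer_high = NA_real_,
                 nmb_low = NA_real_, nmb_high = NA_real_, spread = NA_real_,
                 error = conditionMessage(e))
    })
    res
  })
  out <- do.call(rbind, rows)
  ok <- is.na(out$error) & out$icer_low > 0 & out$icer_high > 0
  out$base_between <- ifelse(
    ok, (pmin(out$icer_low, out$icer_high) <= base_icer + 1e-6) &
        (base_icer - 1e-6 <= pmax(out$icer_low, out$icer_high)), NA)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  attr(out, "wtp") <- config$wtp_per_qaly
  class(out) <- c("dsa_result", "data.frame")
  out
}

#' Parameters whose lower- or upper-limit run is cost-effective
#'
#' Cost-effective means a positive QALY gain with ICER below the
#' willingness-to-pay threshold, i.e. positive net monetary benefit.
#'
#' @param dsa A [run_dsa()] result.
#' @param limit `"low"` or `"high"`.
#' @export
dsa_crossers <- function(dsa, limit = c("low", "high")) {
  limit <- match.arg(limit)
  nmb_col <- if (limit == "low") dsa$nmb_low else dsa$nmb_high
  sort(dsa$name[!is.na(nmb_col) & nmb_col >= 0])
}

#' Tornado diagram of the one-way sensitivity analysis
#'
#' @param dsa A [run_dsa()] result.
#' @param top Number of parameters shown (by decreasing spread).
#' @return A ggplot object.
#' @export
plot_tornado <- function(dsa, top = 10) {
  stopifnot(inherits(dsa, "dsa_result"))
  d <- dsa[!is.na(dsa$spread), ]
  d <- utils::head(d[order(-d$spread), ], top)
  d$name <- factor(d$name, levels = rev(d$name))
  base_icer <- attr(dsa, "base_icer")
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low, xend = .data$icer_high,
                                       y = .data$name, yend = .data$name),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base_icer, linetype = 2) +
    ggplot2::geom_vline(xintercept = attr(dsa, "wtp"), colour = "firebrick") +
    ggplot2::labs(x = "ICER (US$/QALY)", y = NULL,
                  title = "One-way sensitivity analysis",
                  subtitle = "dashed: base-case ICER; red: WTP threshold") +
    ggplot2::theme_minimal()
}
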