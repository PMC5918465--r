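#' Volcano-style overview of a chunked analysis
#'
#' Plots each candidate combination at (support, -log10 raw p), coloured
#' by final significance, with the aggregated threshold
#' `alpha / total_k` as a dashed line.
#'
#' @param object A `lamp_report` from [run_chunked()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lamp_report
#' @export
autoplot.lamp_report <- function(object, ...) {
  res <- object$results
  if (nrow(res) == 0L) {
    abort("report has no candidate combinations to plot.")
  }
  res$raw_p <- pmax(res$raw_p, .Machine$double.xmin)
  ggplot2::ggplot(res, ggplot2::aes(x = .data$support, y = -log10(.data$raw_p),
                                    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(object$alpha / object$total_k),
                        linetype = "dashed") +
    ggplot2::labs(
      x = "support (number of carrier samples)",
      y = expression(-log[10] ~ "raw log-rank p"),
      colour = sprintf("p * k < %g", object$alpha),
      title = sprintf("Candidate combinations (total k = %d)", object$total_k)
    ) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves for carriers of a combination
#'
#' Convenience display: survival curves of samples carrying every marker
#' of the combination versus the rest, estimated with
#' [survival::survfit()].
#'
#' @param ds A `survlamp_dataset`.
#' @param markers Character vector of marker ids.
#' @return A ggplot object.
#' @export
plot_pattern_survival <- function(ds, markers) {
  mask <- carrier_mask(ds, markers)
  if (all(mask) || !any(mask)) {
    abort("combination splits the samples into a single group; nothing to compare.")
  }
  dat <- data.frame(
    time = ds$clinical$time,
    event = ds$clinical$event,
    group = factor(ifelse(mask, "carrier", "non-carrier"),
                   levels = c("carrier", "non-carrier"))
  )
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  strata <- rep(names(fit$strata), fit$strata)
  km <- dplyr::bind_rows(
    tibble(time = 0, surv = 1, group = unique(strata)),
    tibble(time = fit$time, surv = fit$surv, group = strata)
  )
  km$group <- sub("^group=", "", km$group)
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "time (months)", y = "survival probability", colour = NULL,
      title = paste(c_sort(unique(as.character(markers))), collapse = ",")
    ) +
    ggplot2::theme_minimal()
}
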