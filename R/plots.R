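#' @export
autoplot.srd_result <- function(object, crrn = NULL, ...) {
  dat <- dplyr::arrange(tibble::as_tibble(object), .data$srd_pct)
  dat$measure <- factor(dat$measure, levels = dat$measure)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$srd_pct, y = .data$measure)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "SRD (% of maximum)", y = NULL,
                  title = "Distance of each measure from the consensus ranking")
  if (!is.null(crrn)) {
    stopifnot(inherits(crrn, "crrn_dist"))
    p <- p +
      ggplot2::geom_vline(xintercept = c(crrn$q5, crrn$median, crrn$q95),
                          linetype = c("dashed", "solid", "dashed"),
                          colour = "firebrick") +
      ggplot2::labs(subtitle = sprintf(
        "Random-ranking null: median %.1f%%, 5-95%% band dashed", crrn$median))
  }
  p
}

#' @export
autoplot.srd_cv <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  med <- dplyr::summarise(dplyr::group_by(dat, .data$measure),
                          med = median(.data$srd_pct))
  dat$measure <- factor(dat$measure,
                        levels = med$measure[order(med$med)])
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$measure, y = .data$srd_pct)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1)) +
    ggplot2::labs(x = NULL, y = "SRD (% of maximum)",
                  title = "Sevenfold cross-validated SRD per measure")
}

#' @export
autoplot.crrn_dist <- function(object, ...) {
  dat <- object$dist
  if (object$method == "exact") {
    dat <- tibble::tibble(srd_pct = 100 * dat$srd / object$srd_max,
                          weight = dat$prob)
    ggplot2::ggplot(dat, ggplot2::aes(x = .data$srd_pct, y = .data$weight)) +
      ggplot2::geom_col(width = 100 / object$srd_max, fill = "grey35") +
      ggplot2::labs(x = "SRD (% of maximum)", y = "probability",
                    title = sprintf("Exact CRRN null, n = %d", object$n))
  } else {
    dat <- tibble::tibble(srd_pct = 100 * dat$srd / object$srd_max)
    ggplot2::ggplot(dat, ggplot2::aes(x = .data$srd_pct)) +
      ggplot2::geom_histogram(binwidth = 100 / object$srd_max,
                              fill = "grey35") +
      ggplot2::labs(x = "SRD (% of maximum)", y = "draws",
                    title = sprintf("Monte-Carlo CRRN null, n = %d (%d draws)",
                                    object$n, object$n_sim))
  }
}

#' @export
autoplot.ga_pls_result <- function(object, ...) {
  dat <- dplyr::arrange(object$pct_selection, dplyr::desc(.data$pct))
  dat$descriptor <- factor(dat$descriptor, levels = dat$descriptor)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$descriptor, y = .data$pct)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = mean(dat$pct), linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1)) +
    ggplot2::labs(x = NULL, y = "% selection",
                  title = "GA-PLS descriptor selection frequency",
                  subtitle = "dashed line: mean % selection (consensus threshold)")
}

#' @export
autoplot.consensus_qsrr <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$y, y = .data$y_hat,
                               colour = .data$set)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "observed", y = "predicted",
                  title = sprintf("Consensus GA-PLS model (%d descriptors, %d LV)",
                                  length(object$consensus), object$lv))
}
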