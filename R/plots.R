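#' Plot a disease profile's Gaussian models
#'
#' Onset, death and duration densities for one disease, each on its own
#' support, faceted by variable.
#'
#' @param object A `disease_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot disease_profile
#' @export
autoplot.disease_profile <- function(object, ...) {
  pieces <- keep(list(onset = object$onset, death = object$death,
                      duration = object$duration),
                 ~ !is.null(.x) && !is.null(.x$model))
  if (length(pieces) == 0L) abort("profile has no fitted Gaussian models")
  df <- bind_rows(imap(pieces, function(p, nm) {
    xs <- seq(p$model$support[1], p$model$support[2], length.out = 200)
    tibble(variable = nm, years = xs, density = model_density(p$model, xs))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$years, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free") +
    ggplot2::labs(title = paste0(object$disease, " pooled Gaussian models"),
                  x = "years", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix as a proportion heatmap
#'
#' Tile map of the missed-diagnosis view (each pathological column normalised
#' to 1) or the misdiagnosis view, with counts overlaid.
#'
#' @param object A `confusion_matrix`.
#' @param direction Normalisation direction (see [misdiagnosis_rates()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot confusion_matrix
#' @export
autoplot.confusion_matrix <- function(object,
                                      direction = "path_to_clinical", ...) {
  rates <- misdiagnosis_rates(object, direction)
  df <- as_tibble(as.data.frame.table(rates, responseName = "proportion",
                                      stringsAsFactors = FALSE))
  df$count <- as.vector(object$counts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pathological, y = .data$clinical,
                                   fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 na.value = "grey90") +
    ggplot2::labs(x = "pathological diagnosis", y = "clinical diagnosis",
                  fill = "proportion") +
    ggplot2::theme_minimal()
}

#' Plot per-disease diagnostic probabilities
#'
#' Bar chart of the normalised posterior with the unnormalised per-disease
#' probability overlaid as points.
#'
#' @param object A `diagnostic_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot diagnostic_result
#' @export
autoplot.diagnostic_result <- function(object, ...) {
  d <- mutate(object$diseases,
              disease = factor(.data$disease,
                               levels = .data$disease[order(-.data$posterior)]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$disease, y = .data$posterior)) +
    ggplot2::geom_col(fill = "steelblue", alpha = 0.8) +
    ggplot2::geom_point(ggplot2::aes(y = .data$probability)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "posterior (bars) / per-disease probability (points)",
                  x = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cumulative survival curves from duration models
#'
#' @param models Named list of `gaussian_model`s fitted to disease duration.
#' @return A ggplot of `P(survival > t)` with the 50% point marked.
#' @export
plot_survival <- function(models) {
  df <- bind_rows(imap(models, function(m, nm) {
    xs <- seq(m$support[1], m$support[2], length.out = 200)
    tibble(disease = nm, years = xs, survival = survival_probability(m, xs))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$years, y = .data$survival,
                                   colour = .data$disease)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "years from symptom onset",
                  y = "cumulative probability of survival") +
    ggplot2::theme_minimal()
}
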