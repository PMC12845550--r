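# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an object classifier
#'
#' One row per (class, descriptor component) coefficient.
#'
#' @param x An `object_classifier`.
#' @param ... Unused.
#' @return Tibble with class, term, estimate.
#' @method tidy object_classifier
#' @export
tidy.object_classifier <- function(x, ...) {
  W <- x$fit$W
  tibble(class = rep(x$classes, times = ncol(W)),
         term = rep(sprintf("f%03d", seq_len(ncol(W))), each = nrow(W)),
         estimate = as.vector(W))
}

#' @method glance object_classifier
#' @export
glance.object_classifier <- function(x, ...) {
  tibble(n_classes = length(x$classes), n_train = x$n_train, n_val = x$n_val,
         train_accuracy = x$train_accuracy, val_accuracy = x$val_accuracy,
         epochs = x$epochs, final_loss = tail(x$fit$history, 1))
}

#' Tidy an SGG model
#'
#' Per-relation coefficient norms of the two trained branches (the class
#' branch has no free parameters).
#'
#' @param x An `sgg_model`.
#' @param ... Unused.
#' @return Tibble with relation, branch, coef_norm.
#' @method tidy sgg_model
#' @export
tidy.sgg_model <- function(x, ...) {
  bind_rows(
    tibble(relation = x$relations, branch = "feature",
           coef_norm = sqrt(rowSums(x$W_f^2))),
    tibble(relation = x$relations, branch = "context",
           coef_norm = sqrt(rowSums(x$W_c^2)))
  )
}

#' @method glance sgg_model
#' @export
glance.sgg_model <- function(x, ...) {
  tibble(species = x$species, n_relations = length(x$relations),
         n_pairs = x$n_pairs, epochs = x$epochs, lr = x$lr,
         final_loss = tail(x$history, 1),
         prior_triplets = sum(x$prior$counts))
}

#' @method tidy stage_eval
#' @export
tidy.stage_eval <- function(x, ...) x$verdicts

#' @method glance stage_eval
#' @export
glance.stage_eval <- function(x, ...) {
  tibble(stage = x$stage, accuracy = x$accuracy, n_images = nrow(x$verdicts))
}

#' Plot an accuracy curve report
#'
#' Accuracy versus dataset index for the three evaluation stages.
#'
#' @param object An `eval_report` from [accuracy_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), cols = c("s1", "s2", "s3"),
                              names_to = "stage", values_to = "accuracy")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$dataset, y = .data$accuracy,
                                     color = toupper(.data$stage))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "dataset index", y = "accuracy", color = "stage") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a scene image with its boxes
#'
#' @param image A `scene_image`.
#' @param annotation Optional `image_annotation` whose object boxes are drawn.
#' @return A ggplot object (raster + box outlines).
#' @export
plot_scene <- function(image, annotation = NULL) {
  px <- image$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  df <- expand.grid(y = seq_len(h), x = seq_len(w))
  df$col <- grDevices::rgb(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$col)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(annotation) && nrow(annotation$objects) > 0L) {
    b <- annotation$objects
    p <- p + ggplot2::geom_rect(
      data = b, inherit.aes = FALSE, fill = NA, color = "red",
      ggplot2::aes(xmin = .data$x + 0.5, xmax = .data$x + .data$w + 0.5,
                   ymin = .data$y + 0.5, ymax = .data$y + .data$h + 0.5))
  }
  p
}
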