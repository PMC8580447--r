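#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a subdivision model
#'
#' One row per subdivision with its temporal structure (hours covered, modal
#' onset/offset, circular onset s.d.).
#'
#' @param x A `subdivision_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy subdivision_model
#' @export
tidy.subdivision_model <- function(x, ...) {
  x$clusters
}

#' @rdname tidy.subdivision_model
#' @return For `glance`: a one-row tibble with `k`, `inertia`,
#'   `cyclic_order_ok`, `restarts`, `seed`.
#' @method glance subdivision_model
#' @export
glance.subdivision_model <- function(x, ...) {
  tibble::tibble(k = x$k, inertia = x$inertia,
                 cyclic_order_ok = x$cyclic_order_ok,
                 restarts = x$restarts, seed = x$seed)
}

#' Tidy preference statistics
#'
#' @param x A `preference_stats` table.
#' @param ... Unused.
#' @return The underlying tibble (already one row per subdivision).
#' @method tidy preference_stats
#' @export
tidy.preference_stats <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "preference_stats")
  out
}

#' @rdname tidy.preference_stats
#' @return For `glance`: one row with the number of subdivisions tested and
#'   how many are significant at 0.05 after correction.
#' @method glance preference_stats
#' @export
glance.preference_stats <- function(x, ...) {
  tibble::tibble(n_subdivisions = nrow(x),
                 n_significant = sum(x$p < 0.05),
                 min_p = min(x$p))
}

#' Glance at a trained classifier
#'
#' @param x A `diurnal_mlp`.
#' @param ... Unused.
#' @return One-row tibble of training metrics.
#' @method glance diurnal_mlp
#' @export
glance.diurnal_mlp <- function(x, ...) {
  tibble::tibble(holdout_accuracy = x$metrics$holdout_accuracy,
                 holdout_loss = x$metrics$holdout_loss,
                 validation_accuracy = x$metrics$validation_accuracy,
                 epochs_run = x$metrics$epochs_run,
                 best_epoch = x$metrics$best_epoch,
                 seed = x$seed)
}

#' @rdname glance.diurnal_mlp
#' @return For `tidy`: per-class holdout accuracy.
#' @method tidy diurnal_mlp
#' @export
tidy.diurnal_mlp <- function(x, ...) {
  x$metrics$per_class_accuracy
}
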