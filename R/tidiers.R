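#' @importFrom generics tidy glance
NULL

#' Tidy a replication into one row per statistics entry
#'
#' @param x A `"fog_replication"`.
#' @param table Which table to tidy: `"position"`, `"m1_point"`,
#'   `"m2_point"`, `"m1_participant"` or `"m2_participant"`.
#' @param ... Unused.
#' @return A tibble in long format.
#' @export
tidy.fog_replication <- function(x, table = c("position", "m1_point",
                                              "m2_point", "m1_participant",
                                              "m2_participant"), ...) {
  table <- match.arg(table)
  tb <- x$tables
  pick <- switch(table,
    position = tb$position_per_point,
    m1_point = tb$m1_per_point,
    m2_point = tb$m2_per_point,
    m1_participant = dplyr::bind_rows(tb$m1_per_participant, .id = "condition"),
    m2_participant = dplyr::bind_rows(tb$m2_per_participant, .id = "condition")
  )
  tibble::as_tibble(pick)
}

#' One-row summary of a replication
#'
#' @param x A `"fog_replication"`.
#' @param ... Unused.
#' @return A one-row tibble with the headline accuracy figures.
#' @export
glance.fog_replication <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_participants = x$n_participants,
    n_stops = s$n_stops,
    position_rmse_x = unname(s$position_rmse["x"]),
    position_rmse_y = unname(s$position_rmse["y"]),
    position_rmse_worst = unname(s$position_rmse["worst"]),
    m1_max_point_rmse = s$m1_max_point_rmse %||% NA_real_,
    m2_max_point_rmse = s$m2_max_point_rmse %||% NA_real_,
    m2_max_participant_rmse_p2 = s$m2_max_participant_rmse_p2 %||% NA_real_,
    n_confirmations = s$n_confirmations,
    runtime_s = s$runtime_s
  )
}

#' Tidy a trained heading classifier into a coefficient-style tibble
#'
#' @param x A `"heading_classifier"`.
#' @param ... Unused.
#' @return Tibble with one row per layer describing its dimensions and
#'   weight scale.
#' @export
tidy.heading_classifier <- function(x, ...) {
  tibble::tibble(
    layer = c("hidden", "output"),
    inputs = c(nrow(x$W1), nrow(x$W2)),
    units = c(ncol(x$W1), ncol(x$W2)),
    weight_rms = c(sqrt(mean(x$W1^2)), sqrt(mean(x$W2^2)))
  )
}

#' One-row summary of a trained heading classifier
#'
#' @param x A `"heading_classifier"`.
#' @param ... Unused.
#' @return A one-row tibble with the topology and training metadata.
#' @export
glance.heading_classifier <- function(x, ...) {
  tibble::tibble(
    n_inputs = nrow(x$W1), n_hidden = ncol(x$W1), n_classes = ncol(x$W2),
    epochs = x$meta$epochs, lr = x$meta$lr, batch = x$meta$batch,
    n_train = x$meta$n_train, seed = x$meta$seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
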