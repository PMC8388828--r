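#' Tidy host predictions into one row per virus-taxon score
#'
#' @param x A `vh_host_predictions` object.
#' @param ... Unused.
#' @return A tibble `virus_id`, `taxon_id`, `evidence_types`, `score`.
#' @method tidy vh_host_predictions
#' @export
tidy.vh_host_predictions <- function(x, ...) {
  ev <- attr(x, "evidence")
  if (is.null(ev) || nrow(ev) == 0) {
    return(tibble::tibble(virus_id = character(), taxon_id = character(),
                          evidence_types = character(), score = numeric()))
  }
  sc <- score_consensus(ev)
  types <- ev |>
    dplyr::distinct(.data$virus_id, .data$taxon_id, .data$evidence_type) |>
    dplyr::group_by(.data$virus_id, .data$taxon_id) |>
    dplyr::summarise(
      evidence_types = paste(sort(.data$evidence_type), collapse = "+"),
      .groups = "drop")
  dplyr::left_join(types, sc, by = c("virus_id", "taxon_id")) |>
    dplyr::arrange(.data$virus_id, dplyr::desc(.data$score))
}

#' One-row summary of a host-prediction run
#'
#' @param x A `vh_host_predictions` object.
#' @param ... Unused.
#' @return A tibble with `n_viruses`, `n_resolved`, `n_tied`,
#'   `mean_score`.
#' @method glance vh_host_predictions
#' @export
glance.vh_host_predictions <- function(x, ...) {
  tibble::tibble(
    n_viruses = nrow(x),
    n_resolved = sum(!x$tie),
    n_tied = sum(x$tie),
    mean_score = mean(x$score)
  )
}

#' Tidy a Mantel test result
#'
#' @param x A `vh_mantel` object.
#' @param ... Unused.
#' @return A one-row tibble `statistic`, `p_value`, `n_permutations`.
#' @method tidy vh_mantel
#' @export
tidy.vh_mantel <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 n_permutations = x$n_permutations)
}

#' @rdname tidy.vh_mantel
#' @method glance vh_mantel
#' @export
glance.vh_mantel <- tidy.vh_mantel

#' Tidy a community partition into per-sample category fractions
#'
#' @param x A `vh_partition` object.
#' @param ... Unused.
#' @return The `fractions` tibble.
#' @method tidy vh_partition
#' @export
tidy.vh_partition <- function(x, ...) {
  x$fractions
}

#' One-row-per-category summary of a partition
#'
#' @param x A `vh_partition` object.
#' @param ... Unused.
#' @return A tibble `category`, `n_features`.
#' @method glance vh_partition
#' @export
glance.vh_partition <- function(x, ...) {
  dplyr::count(x$categories, .data$category, name = "n_features")
}

#' @export
print.vh_partition <- function(x, ...) {
  lab <- if (x$grouping == "site") {
    sprintf("site sharing in %s", x$season)
  } else {
    sprintf("season sharing at %s", x$site)
  }
  cat(sprintf("Community partition (%s): %d features in %d categories\n",
              lab, nrow(x$categories),
              length(unique(x$categories$category))))
  print(glance.vh_partition(x))
  invisible(x)
}
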