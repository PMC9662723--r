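# Tidy accessors and plotting for resolution results.

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Summarize a batch resolution
#'
#' @param x A `pd_results` tibble from [resolve_political_divisions()].
#' @param ... Unused.
#' @return One-row tibble: row counts and proportions by match status, the
#'   mean overall score, and the threshold used.
#' @method glance pd_results
#' @export
glance.pd_results <- function(x, ...) {
  n <- nrow(x)
  n_full <- sum(x$match_status == "full match")
  n_partial <- sum(x$match_status == "partial match")
  n_no <- sum(x$match_status == "no match")
  tibble::tibble(
    n = n,
    n_full = n_full, n_partial = n_partial, n_no_match = n_no,
    pct_full = if (n > 0L) 100 * n_full / n else NA_real_,
    pct_partial = if (n > 0L) 100 * n_partial / n else NA_real_,
    pct_no_match = if (n > 0L) 100 * n_no / n else NA_real_,
    mean_overall_score = if (n > 0L) mean(x$overall_score) else NA_real_,
    tfuzzy = attr(x, "tfuzzy") %||% NA_real_
  )
}

#' Per-level long view of a batch resolution
#'
#' @param x A `pd_results` tibble.
#' @param ... Unused.
#' @return Tibble with one row per (record, level): `row`, `user_id`,
#'   `level`, `verbatim`, `matched`, `method`, `score`.
#' @method tidy pd_results
#' @export
tidy.pd_results <- function(x, ...) {
  base <- tibble::tibble(row = seq_len(nrow(x)), user_id = x$user_id)
  one <- function(level, verbatim, matched, method, score) {
    dplyr::bind_cols(base, tibble::tibble(
      level = level, verbatim = x[[verbatim]], matched = x[[matched]],
      method = x[[method]], score = x[[score]]
    ))
  }
  out <- dplyr::bind_rows(
    one(
      "country", "country_verbatim", "country",
      "match_method_country", "match_score_country"
    ),
    one(
      "state_province", "state_province_verbatim", "state_province",
      "match_method_state_province", "match_score_state_province"
    ),
    one(
      "county_parish", "county_parish_verbatim", "county_parish",
      "match_method_county_parish", "match_score_county_parish"
    )
  )
  out <- out[nzchar(out$verbatim) | nzchar(out$matched), , drop = FALSE]
  dplyr::arrange(out, .data$row, match(.data$level, pd_levels))
}

#' Plot match-status composition of a batch resolution
#'
#' @param object A `pd_results` tibble.
#' @param ... Unused.
#' @return A ggplot bar chart of record counts by match status.
#' @method autoplot pd_results
#' @export
autoplot.pd_results <- function(object, ...) {
  df <- tibble::tibble(
    match_status = factor(
      object$match_status,
      levels = c("full match", "partial match", "no match")
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$match_status)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(
      x = "match status", y = "records",
      title = "Political division resolution outcomes"
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.pd_results <- function(x, ...) {
  print(autoplot(x, ...))
  invisible(x)
}
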