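# Name normalization and the trigram similarity metric.
#
# All matching inside the package happens on "folded" strings: plain-ascii,
# lowercase, punctuation collapsed to single spaces. Fuzzy matching uses the
# Jaccard coefficient of padded character 3-gram sets, with each word padded
# by two leading spaces and one trailing space before windows are taken.

pd_levels <- c("country", "state_province", "county_parish")

#' Fold a name to its plain-ascii matching form
#'
#' Applies unicode compatibility decomposition, removes combining marks,
#' lowercases, maps every character outside `[a-z0-9]` to a single space,
#' collapses runs of spaces and trims. This is the canonical form used for
#' all exact and fuzzy comparisons; it is idempotent.
#'
#' @param x Character vector of verbatim names. `NA` is treated as `""`.
#' @return Character vector of folded names, same length as `x`.
#' @examples
#' fold_name(c("México", "Upper Takutu-Upper Essequibo"))
#' @export
fold_name <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  out <- x
  nz <- nzchar(x)
  if (any(nz)) {
    y <- stringi::stri_trans_general(x[nz], "Any-NFKD")
    y <- stringi::stri_replace_all_regex(y, "\\p{Mn}+", "")
    y <- stringi::stri_trans_tolower(y)
    y <- stringi::stri_replace_all_regex(y, "[^a-z0-9]+", " ")
    out[nz] <- stringi::stri_trim_both(y)
  }
  out
}

#' Remove administrative class identifiers from a folded name
#'
#' Class identifiers are division-type words attached to a name ("State of",
#' "Provincia de", "Oblast", "County", and abbreviations such as "Distr.").
#' At most one prefix sequence and one suffix sequence are removed, longest
#' match first, restricted to lexicon entries whose `level_scope` is the
#' given level or `"any"`. If removal would empty the string the input is
#' returned unchanged, so a bare class word ("County") survives.
#'
#' @param x Character vector of already-folded names.
#' @param level One of `"country"`, `"state_province"`, `"county_parish"`.
#' @param lexicon Data frame with columns `token_sequence` (folded words),
#'   `position` (`"prefix"`, `"suffix"` or `"either"`) and `level_scope`.
#' @return Character vector of stripped names.
#' @examples
#' lex <- tibble::tibble(
#'   token_sequence = c("provincia de", "county"),
#'   position = c("prefix", "suffix"),
#'   level_scope = c("state_province", "county_parish")
#' )
#' strip_class_identifiers("pima county", "county_parish", lex)
#' @export
strip_class_identifiers <- function(x, level, lexicon) {
  level <- rlang::arg_match(level, pd_levels)
  stopifnot(is.data.frame(lexicon))
  lex <- lexicon[lexicon$level_scope %in% c(level, "any"), , drop = FALSE]
  if (nrow(lex) == 0L) {
    return(x)
  }
  seqs <- strsplit(lex$token_sequence, " ", fixed = TRUE)
  ord <- order(lengths(seqs), decreasing = TRUE)
  vapply(x, strip_one, character(1),
    seqs = seqs[ord], pos = lex$position[ord],
    USE.NAMES = FALSE
  )
}

strip_one <- function(s, seqs, pos) {
  if (is.na(s) || !nzchar(s)) {
    return(s)
  }
  words <- strsplit(s, " ", fixed = TRUE)[[1]]
  out <- words
  for (i in seq_along(seqs)) {
    if (!pos[i] %in% c("prefix", "either")) next
    k <- length(seqs[[i]])
    if (k <= length(out) && identical(out[seq_len(k)], seqs[[i]])) {
      out <- out[-seq_len(k)]
      break
    }
  }
  n <- length(out)
  for (i in seq_along(seqs)) {
    if (!pos[i] %in% c("suffix", "either")) next
    k <- length(seqs[[i]])
    if (k <= n && n > 0L && identical(out[seq.int(n - k + 1L, n)], seqs[[i]])) {
      out <- out[-seq.int(n - k + 1L, n)]
      break
    }
  }
  if (length(out) == 0L) s else paste(out, collapse = " ")
}

#' Padded character trigrams of a folded string
#'
#' Each word is padded with two leading spaces and one trailing space and all
#' 3-character windows are taken; the result is the set union across words.
#'
#' @param x A single folded string.
#' @return Character vector of distinct trigrams (empty for empty input).
#' @examples
#' name_trigrams("abc") # "  a", " ab", "abc", "bc "
#' @export
name_trigrams <- function(x) {
  stopifnot(length(x) == 1L)
  if (is.na(x) || !nzchar(x)) {
    return(character(0))
  }
  words <- strsplit(x, " ", fixed = TRUE)[[1]]
  words <- words[nzchar(words)]
  if (length(words) == 0L) {
    return(character(0))
  }
  padded <- paste0("  ", words, " ")
  grams <- unlist(lapply(padded, function(w) {
    stringi::stri_sub(w, seq_len(stringi::stri_length(w) - 2L), length = 3L)
  }), use.names = FALSE)
  unique(grams)
}

#' Trigram similarity between two folded strings
#'
#' Jaccard coefficient of the padded trigram sets of `a` and `b`:
#' `|T(a) n T(b)| / |T(a) u T(b)|`. Defined as 1 when both sets are empty and
#' 0 when exactly one is empty. Callers are expected to [fold_name()] first.
#'
#' @param a,b Folded strings.
#' @return Similarity score in `[0, 1]`.
#' @examples
#' trigram_similarity("arizona", "arizonna")
#' @export
trigram_similarity <- function(a, b) {
  sim_grams(name_trigrams(a), name_trigrams(b))
}

# Jaccard on two precomputed gram sets (character vectors of unique grams).
sim_grams <- function(ga, gb) {
  na <- length(ga)
  nb <- length(gb)
  if (na == 0L && nb == 0L) {
    return(1)
  }
  if (na == 0L || nb == 0L) {
    return(0)
  }
  i <- sum(ga %in% gb)
  i / (na + nb - i)
}
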