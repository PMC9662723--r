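# Shared fixture world and independent oracles.
#
# The trigram oracle below is deliberately written with a different
# mechanism (per-character substring loops and set operations) than the
# package implementation, so the two can cross-check each other.

the_fixture <- new.env(parent = emptyenv())

fixture_dir <- function() {
  if (is.null(the_fixture$dir)) {
    d <- file.path(tempdir(), "poldiv-fixture-world")
    generate_fixture_world(d, seed = 42L, n_extra = 40L)
    the_fixture$dir <- d
  }
  the_fixture$dir
}

fixture_world <- function() {
  if (is.null(the_fixture$world)) {
    the_fixture$world <- load_ref_world(fixture_dir())
  }
  the_fixture$world
}

fixture_manifest <- function() {
  if (is.null(the_fixture$manifest)) {
    d <- file.path(tempdir(), "poldiv-fixture-manifest")
    the_fixture$manifest <- generate_fixture_world(d, seed = 42L, n_extra = 40L)
  }
  the_fixture$manifest
}

# --- independent trigram oracle -------------------------------------------

oracle_trigrams <- function(s) {
  words <- unlist(strsplit(s, "[ ]+"))
  words <- words[nchar(words) > 0]
  grams <- character(0)
  for (w in words) {
    p <- paste0("  ", w, " ")
    for (k in seq_len(nchar(p) - 2L)) {
      grams <- c(grams, substring(p, k, k + 2L))
    }
  }
  unique(grams)
}

oracle_similarity <- function(a, b) {
  ta <- oracle_trigrams(a)
  tb <- oracle_trigrams(b)
  if (length(ta) == 0L && length(tb) == 0L) {
    return(1)
  }
  u <- union(ta, tb)
  length(intersect(ta, tb)) / length(u)
}

# --- random inputs ---------------------------------------------------------

rand_folded_string <- function(max_len = 14L) {
  n <- sample(0:max_len, 1L)
  if (n == 0L) {
    return("")
  }
  paste0(
    sample(c(letters, " "), n, replace = TRUE, prob = c(rep(1, 26), 4)),
    collapse = ""
  )
}

# One random character edit (substitution, insertion or deletion) applied to
# a folded name; the result is re-folded.
perturb_name <- function(folded, n_edits = 1L) {
  for (e in seq_len(n_edits)) {
    chars <- strsplit(folded, "")[[1]]
    pos <- sample(seq_along(chars), 1L)
    op <- sample(c("sub", "ins", "del"), 1L)
    if (op == "sub") {
      chars[pos] <- sample(letters, 1L)
    } else if (op == "ins") {
      chars <- append(chars, sample(letters, 1L), after = pos)
    } else if (length(chars) > 1L) {
      chars <- chars[-pos]
    }
    folded <- fold_name(paste0(chars, collapse = ""))
  }
  folded
}

# All in-scope name variants at one level, for brute-force comparisons.
scope_variants <- function(world, level, scope) {
  v <- world$variants
  v[v$variant_class %in% c("standard_name", "alternate_name") &
    v$level == level & v$parent_id == scope, , drop = FALSE]
}

# A demo batch in the documented web input format (quoted comma included).
demo_input_lines <- function() {
  c(
    "USA,Arizona,Pima County",
    "México,Oaxaca,",
    "Costa Rica,,",
    "Guyana,Upper Takutu-Upper Essequibo,\"Yakarinta—Wowetta, Surama\""
  )
}
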