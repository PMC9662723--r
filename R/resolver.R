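# The matching cascade.
#
# Each political division combination (PDC) is resolved top-down: country
# first, then state/province within the matched country, then county/parish
# within the matched state. Within one level the cascade is, in strict
# order: (1) code lookup (ISO, FIPS, HASC) on the folded name; (2) exact
# standard-name lookup on the class-identifier-stripped name; (3) exact
# alternate-name lookup on the stripped name; (4) fuzzy trigram match over
# standard names; (5) fuzzy trigram match over alternate names. The first
# stage with a hit wins, so an exact match can never be shadowed by a fuzzy
# one. Two special-case passes remap territories recorded as states
# ("states as countries") and member countries of multinational unions
# recorded as countries ("countries as states").

# cascade evaluation counter, used to verify batch cache semantics
pd_counters <- new.env(parent = emptyenv())
pd_counters$cascades <- 0L

cascade_count <- function() pd_counters$cascades

empty_match <- function() list(entity = NULL, method = "", score = 0)

is_matched <- function(m) !is.null(m$entity)

#' Resolve one name at one level of the hierarchy
#'
#' Runs the five-stage matching cascade for a single verbatim name at one
#' administrative level, within the scope of an already-resolved parent.
#' Exact stages (codes, standard names, alternate names) score 1; fuzzy
#' stages report the trigram similarity between the folded submitted name
#' and the folded matched variant, and only candidates whose similarity to
#' the stripped query reaches `tfuzzy` are eligible. Ties are broken by
#' higher similarity (fuzzy only), then lexicographic standard name, then
#' `entity_id`. Codes are never matched fuzzily.
#'
#' @param world A `ref_world`.
#' @param level `"country"`, `"state_province"` or `"county_parish"`.
#' @param scope `entity_id` of the resolved parent (`""` for countries).
#' @param name Verbatim submitted name (non-empty).
#' @param tfuzzy Fuzzy-match threshold in `[0, 1]`; defaults to 0.5.
#' @return A list with `entity` (one-row tibble or `NULL`), `method` (one of
#'   `"iso code"`, `"fips code"`, `"hasc code"`,
#'   `"exact match standard name"`, `"exact match alternate name"`,
#'   `"fuzzy match standard name"`, `"fuzzy match alternate name"`, or `""`)
#'   and `score` in `[0, 1]`.
#' @export
resolve_level <- function(world, level, scope = "", name, tfuzzy = 0.5) {
  level <- rlang::arg_match(level, pd_levels)
  stopifnot(tfuzzy >= 0, tfuzzy <= 1, nzchar(name))
  pd_counters$cascades <- pd_counters$cascades + 1L

  folded <- fold_name(name)
  stripped <- strip_class_identifiers(folded, level, world$lexicon)
  if (!nzchar(folded)) {
    return(empty_match())
  }

  # (1) codes
  hits <- lookup_code_variants(world, level, scope, folded)
  if (nrow(hits) > 0L) {
    sys <- hits$code_system[1L]
    method <- c(
      iso2 = "iso code", iso3 = "iso code",
      fips = "fips code", hasc = "hasc code"
    )[[sys]]
    return(list(
      entity = entity_by_id(world, hits$entity_id[1L]),
      method = method, score = 1
    ))
  }

  # (2)-(3) exact names on the stripped query
  for (cls in c("standard_name", "alternate_name")) {
    ent <- lookup_name(world, level, scope, stripped, cls)
    if (nrow(ent) > 0L) {
      return(list(
        entity = ent[1L, , drop = FALSE],
        method = paste("exact match", sub("_", " ", cls)),
        score = 1
      ))
    }
  }

  # (4)-(5) fuzzy over names; candidate selection on the stripped query,
  # reported score on the folded (unstripped) query vs the matched variant
  q_grams <- name_trigrams(stripped)
  folded_grams <- name_trigrams(folded)
  v <- world$variants
  for (cls in c("standard_name", "alternate_name")) {
    cand <- v[
      v$variant_class == cls & v$level == level & v$parent_id == scope, ,
      drop = FALSE
    ]
    if (nrow(cand) == 0L) next
    sims <- vapply(cand$grams, sim_grams, numeric(1), ga = q_grams)
    keep <- sims >= tfuzzy
    if (!any(keep)) next
    cand <- cand[keep, , drop = FALSE]
    sims <- sims[keep]
    ord <- order(-sims, cand$standard_name, cand$entity_id)
    best <- cand[ord[1L], , drop = FALSE]
    return(list(
      entity = entity_by_id(world, best$entity_id),
      method = paste("fuzzy match", sub("_", " ", cls)),
      score = sim_grams(folded_grams, best$grams[[1L]])
    ))
  }
  empty_match()
}

find_special_case <- function(world, kind, trigger_name_norm,
                              country_entity = NULL) {
  sc <- world$special_cases
  sc <- sc[sc$kind == kind & sc$trigger_name_norm == trigger_name_norm, ,
    drop = FALSE
  ]
  if (kind == "state_as_country" && nrow(sc) > 0L && !is.null(country_entity)) {
    cn <- fold_name(country_entity$standard_name)
    sc <- sc[!nzchar(sc$trigger_country_norm) | sc$trigger_country_norm == cn, ,
      drop = FALSE
    ]
  }
  if (nrow(sc) == 0L) NULL else sc[1L, , drop = FALSE]
}

# Core of resolve_pdc on verbatim strings; user_id-independent, therefore
# cacheable on (folded country, folded state, folded county, tfuzzy).
resolve_core <- function(world, country, state, county, tfuzzy) {
  cm <- sm <- km <- empty_match()
  notes <- character(0)
  # which output slots carry a submitted (possibly shifted) name and hence
  # enter the overall-score denominator and the match-status rule
  pop <- c(TRUE, nzchar(state), nzchar(county))

  cas <- find_special_case(world, "country_as_state", fold_name(country))
  if (!is.null(cas)) {
    cm <- list(
      entity = entity_by_id(world, cas$target_country_id),
      method = "country as state", score = 1
    )
    sm <- list(
      entity = entity_by_id(world, cas$target_state_id),
      method = "country as state", score = 1
    )
    # the submitted state shifts down one level
    pop <- c(TRUE, FALSE, nzchar(state))
    if (nzchar(state)) {
      km <- resolve_level(
        world, "county_parish", sm$entity$entity_id[1L], state, tfuzzy
      )
    }
    if (nzchar(county)) {
      notes <- c(notes, "county_parish input dropped after country-as-state shift")
    }
  } else {
    cm <- resolve_level(world, "country", "", country, tfuzzy)
    if (is_matched(cm) && nzchar(state)) {
      sm <- resolve_level(
        world, "state_province", cm$entity$entity_id[1L], state, tfuzzy
      )
      if (!is_matched(sm)) {
        sac <- find_special_case(
          world, "state_as_country", fold_name(state),
          country_entity = cm$entity
        )
        if (!is.null(sac)) {
          cm <- list(
            entity = entity_by_id(world, sac$target_country_id),
            method = "state as country", score = 1
          )
          # submitted state is absorbed by the country-level match
          pop <- c(TRUE, FALSE, FALSE)
          if (nzchar(sac$target_state_id)) {
            sm <- list(
              entity = entity_by_id(world, sac$target_state_id),
              method = "state as country", score = 1
            )
            if (nzchar(county)) {
              km <- resolve_level(
                world, "county_parish", sm$entity$entity_id[1L], county, tfuzzy
              )
              pop[3L] <- TRUE
            }
          } else {
            sm <- empty_match()
            if (nzchar(county)) {
              # county shifts up into the state slot under the new country
              sm <- resolve_level(
                world, "state_province", cm$entity$entity_id[1L], county, tfuzzy
              )
              pop[2L] <- TRUE
            }
          }
        }
      } else if (nzchar(county)) {
        km <- resolve_level(
          world, "county_parish", sm$entity$entity_id[1L], county, tfuzzy
        )
      }
    }
  }
  list(country = cm, state = sm, county = km, populated = pop, notes = notes)
}

ent_field <- function(m, field) {
  if (is_matched(m)) m$entity[[field]][1L] else ""
}

result_row <- function(user_id, country, state, county, core) {
  cm <- core$country
  sm <- core$state
  km <- core$county
  pop <- core$populated
  scores <- c(cm$score, sm$score, km$score)
  matched <- c(is_matched(cm), is_matched(sm), is_matched(km))
  n_pop <- sum(pop)
  overall <- if (n_pop > 0L) mean(scores[pop]) else 0
  status <- if (n_pop == 0L || !any(matched[pop])) {
    "no match"
  } else if (all(matched[pop])) {
    "full match"
  } else {
    "partial match"
  }
  submitted <- c(nzchar(country), nzchar(state), nzchar(county))
  poldiv_submitted <- if (any(submitted)) pd_levels[max(which(submitted))] else ""
  poldiv_matched <- if (any(matched)) pd_levels[max(which(matched))] else ""

  tibble::tibble(
    user_id = user_id,
    country_verbatim = country,
    state_province_verbatim = state,
    county_parish_verbatim = county,
    country = ent_field(cm, "standard_name"),
    state_province = ent_field(sm, "standard_name"),
    county_parish = ent_field(km, "standard_name"),
    country_ascii = ent_field(cm, "ascii_name"),
    state_province_ascii = ent_field(sm, "ascii_name"),
    county_parish_ascii = ent_field(km, "ascii_name"),
    country_iso2 = ent_field(cm, "iso_alpha2"),
    country_iso3 = ent_field(cm, "iso_alpha3"),
    state_province_hasc = ent_field(sm, "hasc_code"),
    county_parish_hasc = ent_field(km, "hasc_code"),
    country_geoname_id = ent_field(cm, "geoname_id"),
    state_province_geoname_id = ent_field(sm, "geoname_id"),
    county_parish_geoname_id = ent_field(km, "geoname_id"),
    gid_0 = ent_field(cm, "gadm_gid"),
    gid_1 = ent_field(sm, "gadm_gid"),
    gid_2 = ent_field(km, "gadm_gid"),
    match_method_country = cm$method,
    match_method_state_province = sm$method,
    match_method_county_parish = km$method,
    match_score_country = cm$score,
    match_score_state_province = sm$score,
    match_score_county_parish = km$score,
    overall_score = overall,
    match_status = status,
    poldiv_submitted = poldiv_submitted,
    poldiv_matched = poldiv_matched,
    note = paste(core$notes, collapse = "; ")
  )
}

no_match_row <- function(user_id, country, state, county, note) {
  core <- list(
    country = empty_match(), state = empty_match(), county = empty_match(),
    populated = c(TRUE, nzchar(state), nzchar(county)), notes = note
  )
  result_row(user_id, country, state, county, core)
}

#' Resolve a single political division combination
#'
#' Resolves one (country, state/province, county/parish) combination
#' top-down: the state is only attempted within the matched country and the
#' county only within the matched state; when a higher level fails, lower
#' levels are not attempted and contribute 0 to the overall score.
#'
#' @param world A `ref_world`.
#' @param country Verbatim country name or code (required).
#' @param state_province,county_parish Verbatim lower-level names (optional;
#'   a county requires a state).
#' @param user_id Opaque identifier echoed into the output.
#' @param tfuzzy Fuzzy-match threshold in `[0, 1]`.
#' @return A one-row tibble with the full resolution record: verbatim and
#'   standardized names, ascii names, ISO/HASC codes, gazetteer and spatial
#'   object identifiers (`gid_0`/`gid_1`/`gid_2`), per-level match methods
#'   and scores, `overall_score` (mean per-level score over submitted
#'   levels), `match_status` (`"no match"`, `"partial match"`,
#'   `"full match"`), and the deepest submitted and matched levels.
#' @examples
#' \dontrun{
#' world <- load_ref_world(generate_fixture_world(tempfile())$dir)
#' resolve_pdc(world, "USA", "Arizona", "Pima County")
#' }
#' @export
resolve_pdc <- function(world, country, state_province = "",
                        county_parish = "", user_id = "", tfuzzy = 0.5) {
  stopifnot(inherits(world, "ref_world"), tfuzzy >= 0, tfuzzy <= 1)
  country <- stringr::str_trim(country %|NA|% "")
  state_province <- stringr::str_trim(state_province %|NA|% "")
  county_parish <- stringr::str_trim(county_parish %|NA|% "")
  if (!nzchar(country)) {
    rlang::abort("country is required", class = "poldiv_input_error")
  }
  if (nzchar(county_parish) && !nzchar(state_province)) {
    rlang::abort(
      "a state_province is required when a county_parish is supplied",
      class = "poldiv_input_error"
    )
  }
  core <- resolve_core(world, country, state_province, county_parish, tfuzzy)
  result_row(user_id, country, state_province, county_parish, core)
}

`%|NA|%` <- function(a, b) {
  if (length(a) == 0L || is.na(a)) b else a
}

#' Resolve a batch of political division combinations
#'
#' Data-frame-first batch interface: takes a data frame with columns
#' `country` and optionally `state_province`, `county_parish` and `user_id`,
#' resolves every row against the gazetteer, and returns one output row per
#' input row in input order. Distinct normalized (country, state, county,
#' tfuzzy) keys are resolved once and reused; invalid rows (missing country,
#' county without state) are reported inline with `match_status "no match"`
#' or a demoted county and an explanatory `note`, never by aborting the
#' batch. Results are independent of `cache` and `chunk_size`.
#'
#' @param data Data frame of PDCs; missing columns are treated as empty.
#' @param world A `ref_world`.
#' @param tfuzzy Fuzzy-match threshold in `[0, 1]`; defaults to 0.5.
#' @param cache Reuse results for duplicate normalized keys (default `TRUE`).
#' @param chunk_size Internal batching size (affects progress reporting
#'   only, never results).
#' @param progress Emit a `message()` per chunk.
#' @return A `pd_results` tibble (one row per input row) with the fields
#'   described in [resolve_pdc()] plus `note`; see [data_dictionary()].
#' @examples
#' \dontrun{
#' world <- load_ref_world(generate_fixture_world(tempfile())$dir)
#' tibble::tibble(country = "USA", state_province = "Arizona",
#'                county_parish = "Pima County") |>
#'   resolve_political_divisions(world)
#' }
#' @export
resolve_political_divisions <- function(data, world, tfuzzy = 0.5,
                                        cache = TRUE, chunk_size = 1000L,
                                        progress = FALSE) {
  stopifnot(is.data.frame(data), inherits(world, "ref_world"))
  if (!is.numeric(tfuzzy) || length(tfuzzy) != 1L || is.na(tfuzzy) ||
    tfuzzy < 0 || tfuzzy > 1) {
    rlang::abort("tfuzzy must be a number in [0, 1]",
      class = "poldiv_input_error"
    )
  }
  chunk_size <- max(1L, as.integer(chunk_size))
  n <- nrow(data)
  col <- function(nm) {
    x <- if (nm %in% names(data)) as.character(data[[nm]]) else rep("", n)
    x[is.na(x)] <- ""
    stringr::str_trim(x)
  }
  user_id <- col("user_id")
  country <- col("country")
  state <- col("state_province")
  county <- col("county_parish")

  memo <- new.env(parent = emptyenv())
  resolve_one <- function(i) {
    ctry <- country[i]
    st <- state[i]
    cty <- county[i]
    note <- character(0)
    if (!nzchar(ctry)) {
      return(no_match_row(user_id[i], ctry, st, cty, "invalid record: country is required"))
    }
    if (nzchar(cty) && !nzchar(st)) {
      note <- "county_parish ignored: no state_province submitted"
      cty <- ""
    }
    key <- paste(fold_name(ctry), fold_name(st), fold_name(cty), tfuzzy,
      sep = "\x1f"
    )
    core <- if (cache && !is.null(memo[[key]])) {
      memo[[key]]
    } else {
      res <- resolve_core(world, ctry, st, cty, tfuzzy)
      if (cache) memo[[key]] <- res
      res
    }
    core$notes <- c(note, core$notes)
    result_row(user_id[i], country[i], state[i], county[i], core)
  }

  chunks <- if (n > 0L) split(seq_len(n), (seq_len(n) - 1L) %/% chunk_size) else list()
  rows <- vector("list", length(chunks))
  for (ci in seq_along(chunks)) {
    rows[[ci]] <- dplyr::bind_rows(lapply(chunks[[ci]], resolve_one))
    if (isTRUE(progress)) {
      message(sprintf(
        "poldiv: resolved %d/%d rows", max(chunks[[ci]]), n
      ))
    }
  }
  out <- if (length(rows) > 0L) dplyr::bind_rows(rows) else result_row(
    character(0), character(0), character(0), character(0),
    list(
      country = empty_match(), state = empty_match(), county = empty_match(),
      populated = logical(3), notes = character(0)
    )
  )[0L, ]
  attr(out, "tfuzzy") <- tfuzzy
  class(out) <- c("pd_results", class(out))
  out
}
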