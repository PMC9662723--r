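# Deterministic synthetic gazetteer for tests and demos.
#
# The curated core is a small set of hand-picked divisions with realistic
# codes (real ISO codes are reused for recognizability, without any claim of
# completeness or currency): it covers accented standard names, a hyphenated
# multi-word state, a county name containing a comma and an em-dash,
# alternate names in several languages, and both kinds of special case
# (a territory recorded as a state, member countries of a multinational
# union recorded as countries). Seeded random extras can be appended to
# scale the world up; generation is byte-deterministic for a fixed
# (seed, n_extra).

curated_entities <- function() {
  tibble::tribble(
    ~entity_id, ~level, ~parent_id, ~standard_name, ~ascii_name,
    ~iso_alpha2, ~iso_alpha3, ~fips_code, ~hasc_code, ~geoname_id, ~gadm_gid,
    "usa", "country", "", "United States", "United States",
    "US", "USA", "US", "US", "6252001", "USA",
    "mex", "country", "", "México", "Mexico",
    "MX", "MEX", "MX", "MX", "3996063", "MEX",
    "cri", "country", "", "Costa Rica", "Costa Rica",
    "CR", "CRI", "CS", "CR", "3624060", "CRI",
    "guy", "country", "", "Guyana", "Guyana",
    "GY", "GUY", "GY", "GY", "3378535", "GUY",
    "gbr", "country", "", "United Kingdom", "United Kingdom",
    "GB", "GBR", "UK", "GB", "2635167", "GBR",
    "pri", "country", "", "Puerto Rico", "Puerto Rico",
    "PR", "PRI", "RQ", "PR", "4566966", "PRI",
    "usa-az", "state_province", "usa", "Arizona", "Arizona",
    "", "", "04", "US.AZ", "5551752", "USA.3_1",
    "usa-ca", "state_province", "usa", "California", "California",
    "", "", "06", "US.CA", "5332921", "USA.5_1",
    "mex-oax", "state_province", "mex", "Oaxaca", "Oaxaca",
    "", "", "", "MX.OA", "3522507", "MEX.20_1",
    "guy-ut", "state_province", "guy", "Upper Takutu-Upper Essequibo",
    "Upper Takutu-Upper Essequibo",
    "", "", "", "GY.UT", "3376387", "GUY.9_1",
    "gbr-eng", "state_province", "gbr", "England", "England",
    "", "", "", "GB.EN", "6269131", "GBR.1_1",
    "gbr-sct", "state_province", "gbr", "Scotland", "Scotland",
    "", "", "", "GB.SC", "2638360", "GBR.3_1",
    "usa-az-pima", "county_parish", "usa-az", "Pima", "Pima",
    "", "", "04019", "US.AZ.PM", "5303754", "USA.3.11_1",
    "usa-az-maricopa", "county_parish", "usa-az", "Maricopa", "Maricopa",
    "", "", "04013", "US.AZ.MC", "5303752", "USA.3.7_1",
    "guy-ut-yws", "county_parish", "guy-ut",
    "Yakarinta—Wowetta, Surama", "Yakarinta-Wowetta, Surama",
    "", "", "", "", "", "GUY.9.3_1"
  )
}

curated_variants <- function(ent) {
  std <- tibble::tibble(
    entity_id = ent$entity_id, text = ent$standard_name,
    variant_class = "standard_name", code_system = "none", language = "en"
  )
  alt <- tibble::tribble(
    ~entity_id, ~text, ~language,
    "usa", "United States of America", "en",
    "usa", "Estados Unidos", "es",
    "usa", "États-Unis", "fr",
    "mex", "Mexico", "en",
    "mex", "Estados Unidos Mexicanos", "es",
    "mex", "Mexique", "fr",
    "cri", "Republica de Costa Rica", "es",
    "guy", "British Guiana", "en",
    "gbr", "Great Britain", "en",
    "gbr", "Reino Unido", "es",
    "gbr", "Royaume-Uni", "fr",
    "pri", "Porto Rico", "fr",
    "usa-az", "Ariz.", "en",
    "usa-az", "State of Arizona", "en",
    "usa-ca", "Calif.", "en",
    "mex-oax", "Estado Libre y Soberano de Oaxaca", "es",
    "guy-ut", "Region 9", "en",
    "usa-az-pima", "Pima County", "en"
  )
  alt$variant_class <- "alternate_name"
  alt$code_system <- "none"
  # subdivision codes carried as explicit code variants (ISO 3166-2 style)
  codes <- tibble::tribble(
    ~entity_id, ~text, ~code_system,
    "usa-az", "AZ", "iso2",
    "usa-ca", "CA", "iso2",
    "mex-oax", "OAX", "iso3"
  )
  codes$variant_class <- "code"
  codes$language <- ""
  dplyr::bind_rows(std, alt, codes)[
    , c("entity_id", "text", "variant_class", "code_system", "language")
  ]
}

curated_special_cases <- function() {
  tibble::tribble(
    ~kind, ~trigger_country, ~trigger_name, ~target_country_id, ~target_state_id,
    "state_as_country", "United States", "Puerto Rico", "pri", "",
    "country_as_state", "", "England", "gbr", "gbr-eng",
    "country_as_state", "", "Scotland", "gbr", "gbr-sct"
  )
}

curated_lexicon <- function() {
  tibble::tribble(
    ~token_sequence, ~position, ~level_scope,
    "state of", "prefix", "state_province",
    "provincia de", "prefix", "state_province",
    "departamento de", "prefix", "state_province",
    "departement de", "prefix", "state_province",
    "departement", "either", "state_province",
    "oblast", "either", "state_province",
    "obl", "either", "state_province",
    "prefecture", "either", "any",
    "pref", "either", "any",
    "district", "either", "county_parish",
    "distr", "either", "county_parish",
    "county", "suffix", "county_parish",
    "cty", "suffix", "county_parish",
    "parish", "suffix", "county_parish",
    "municipio de", "prefix", "county_parish"
  )
}

curated_meta <- function() {
  tibble::tribble(
    ~source_name, ~version, ~access_date, ~url, ~citation_bibtex,
    "synthetic-fixture-gazetteer", "1.0", "2026-09-27", "",
    "@misc{synthfix, title={Synthetic fixture gazetteer}, year={2026}}",
    "poldiv", "0.1.0", "2026-09-27", "",
    "@misc{poldiv, title={poldiv: political division name standardization}, year={2026}}"
  )
}

# Random extras ------------------------------------------------------------

fixture_syllables <- c(
  "ba", "den", "kor", "lim", "mar", "nov", "pel", "qui", "ran", "sol",
  "tam", "ver", "win", "yar", "zel", "gor", "hul", "ist", "jun", "kam"
)

rand_division_name <- function(used) {
  repeat {
    k <- sample(3:5, 1L)
    s <- paste0(sample(fixture_syllables, k, replace = TRUE), collapse = "")
    s <- paste0(toupper(substr(s, 1L, 1L)), substr(s, 2L, nchar(s)))
    if (!s %in% used) {
      return(s)
    }
  }
}

rand_code <- function(n_chars, used) {
  repeat {
    s <- paste0(sample(LETTERS, n_chars, replace = TRUE), collapse = "")
    if (!s %in% used) {
      return(s)
    }
  }
}

make_extras <- function(n_extra, curated_ent) {
  used_names <- curated_ent$standard_name
  # per-code-system pools; country-level codes must stay unique within the
  # country scope, including against the curated core
  used_iso2 <- curated_ent$iso_alpha2
  used_iso3 <- curated_ent$iso_alpha3
  used_fips <- curated_ent$fips_code
  used_hasc <- curated_ent$hasc_code
  rows <- vector("list", n_extra)
  alt_rows <- list()
  countries <- character(0) # extra country entity ids
  states <- character(0)
  hasc_of <- character(0) # hasc by entity id (extras only)
  gid_of <- character(0)
  kid_count <- integer(0)
  hasc_kids <- list() # used hasc suffixes per parent
  alt_langs <- c("en", "es", "fr", "de", "pt")
  next_geoname <- 9000001L

  kid_hasc <- function(parent) {
    sfx <- rand_code(2L, hasc_kids[[parent]] %||% character(0))
    hasc_kids[[parent]] <<- c(hasc_kids[[parent]], sfx)
    paste0(hasc_of[parent], ".", sfx)
  }

  for (i in seq_len(n_extra)) {
    nm <- rand_division_name(used_names)
    used_names <- c(used_names, nm)
    roll <- stats::runif(1)
    geoname <- as.character(next_geoname)
    next_geoname <- next_geoname + 1L
    if (length(countries) == 0L || roll < 0.3) {
      id <- paste0("x", sprintf("%03d", i))
      iso2 <- rand_code(2L, c(used_iso2, used_hasc))
      used_iso2 <- c(used_iso2, iso2)
      iso3 <- rand_code(3L, used_iso3)
      used_iso3 <- c(used_iso3, iso3)
      fips <- if (stats::runif(1) < 0.7) rand_code(2L, used_fips) else ""
      used_fips <- c(used_fips, fips)
      used_hasc <- c(used_hasc, iso2)
      rows[[i]] <- tibble::tibble(
        entity_id = id, level = "country", parent_id = "",
        standard_name = nm, ascii_name = nm,
        iso_alpha2 = iso2, iso_alpha3 = iso3,
        fips_code = fips,
        hasc_code = iso2,
        geoname_id = geoname,
        gadm_gid = iso3
      )
      countries <- c(countries, id)
      hasc_of[id] <- iso2
      gid_of[id] <- iso3
      kid_count[id] <- 0L
    } else if (length(states) == 0L || roll < 0.65) {
      parent <- sample(countries, 1L)
      kid_count[parent] <- kid_count[parent] + 1L
      id <- paste0("x", sprintf("%03d", i))
      hasc <- kid_hasc(parent)
      gid <- paste0(gid_of[parent], ".", kid_count[parent], "_1")
      rows[[i]] <- tibble::tibble(
        entity_id = id, level = "state_province", parent_id = parent,
        standard_name = nm, ascii_name = nm,
        iso_alpha2 = "", iso_alpha3 = "",
        fips_code = if (stats::runif(1) < 0.4) sprintf("%02d", kid_count[parent]) else "",
        hasc_code = hasc,
        geoname_id = geoname,
        gadm_gid = gid
      )
      states <- c(states, id)
      hasc_of[id] <- hasc
      gid_of[id] <- gid
      kid_count[id] <- 0L
    } else {
      parent <- sample(states, 1L)
      kid_count[parent] <- kid_count[parent] + 1L
      id <- paste0("x", sprintf("%03d", i))
      rows[[i]] <- tibble::tibble(
        entity_id = id, level = "county_parish", parent_id = parent,
        standard_name = nm, ascii_name = nm,
        iso_alpha2 = "", iso_alpha3 = "",
        fips_code = "",
        hasc_code = if (stats::runif(1) < 0.5) kid_hasc(parent) else "",
        geoname_id = geoname,
        gadm_gid = paste0(gid_of[parent], ".", kid_count[parent], "_1")
      )
    }
    n_alt <- sample(0:3, 1L)
    if (n_alt > 0L) {
      alts <- unique(vapply(seq_len(n_alt), function(j) {
        switch(sample(3L, 1L),
          paste0(nm, sample(c("ia", "land", "stan"), 1L)),
          paste0(substr(nm, 1L, max(3L, nchar(nm) - 2L)), "."),
          paste0(sample(c("Santa ", "Nueva ", "Alta "), 1L), nm)
        )
      }, ""))
      alt_rows[[length(alt_rows) + 1L]] <- tibble::tibble(
        entity_id = paste0("x", sprintf("%03d", i)), text = alts,
        variant_class = "alternate_name", code_system = "none",
        language = sample(alt_langs, length(alts), replace = TRUE)
      )
    }
  }
  ent <- dplyr::bind_rows(rows)
  list(entities = ent, alt = dplyr::bind_rows(alt_rows))
}

#' Generate a deterministic fixture gazetteer
#'
#' Writes the five normalized reference tables for a synthetic mini-world to
#' `out_dir`: a curated core (United States/Arizona/Pima, an accented
#' "México" with Oaxaca, Costa Rica, Guyana with a comma-bearing county,
#' a United Kingdom analog with England and Scotland as countries-as-states,
#' and a Puerto Rico analog as a state-as-country under the United States)
#' plus `n_extra` seeded random divisions, each with 0-3 alternate names and
#' plausible codes. Output is byte-identical for a fixed `(seed, n_extra)`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for the random extras.
#' @param n_extra Number of additional random divisions (>= 0).
#' @return Invisibly, the fixture manifest: a list with `dir`, per-table row
#'   `counts`, `n_curated` and `n_extra`.
#' @export
generate_fixture_world <- function(out_dir, seed = 1L, n_extra = 0L) {
  stopifnot(n_extra >= 0L)
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    rlang::abort(paste0("cannot create fixture directory: ", out_dir),
      class = "poldiv_io_error"
    )
  }
  ent <- curated_entities()
  nv <- curated_variants(ent)
  n_curated <- nrow(ent)

  if (n_extra > 0L) {
    extras <- withr::with_seed(as.integer(seed), make_extras(n_extra, ent))
    ent <- dplyr::bind_rows(ent, extras$entities)
    std_extra <- tibble::tibble(
      entity_id = extras$entities$entity_id,
      text = extras$entities$standard_name,
      variant_class = "standard_name", code_system = "none", language = "en"
    )
    nv <- dplyr::bind_rows(nv, std_extra, extras$alt)
  }

  tabs <- list(
    entities = ent[entity_cols],
    name_variants = nv[variant_cols],
    special_cases = curated_special_cases()[special_cols],
    class_identifiers = curated_lexicon()[lexicon_cols],
    meta = curated_meta()[meta_cols]
  )
  for (nm in names(tabs)) {
    readr::write_tsv(tabs[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
      na = "", quote = "none", escape = "none", progress = FALSE
    )
  }
  invisible(list(
    dir = out_dir,
    counts = lapply(tabs, nrow),
    n_curated = n_curated,
    n_extra = as.integer(n_extra)
  ))
}
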