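# Gazetteer reference data model: loading, validation, and indexed lookups.
#
# The on-disk contract is a directory of five tab-delimited UTF-8 tables
# (entities, name_variants, special_cases, class_identifiers, meta). The
# loader validates referential integrity, recomputes every normalized form
# with fold_name() (stored normalized values are never trusted), and builds
# a single variant index used by all lookups: one row per matchable string
# (standard name, alternate name, or code) with its owning entity, level and
# parent scope.

ref_tables <- c(
  "entities", "name_variants", "special_cases", "class_identifiers", "meta"
)

entity_cols <- c(
  "entity_id", "level", "parent_id", "standard_name", "ascii_name",
  "iso_alpha2", "iso_alpha3", "fips_code", "hasc_code", "geoname_id",
  "gadm_gid"
)
variant_cols <- c("entity_id", "text", "variant_class", "code_system", "language")
special_cols <- c(
  "kind", "trigger_country", "trigger_name", "target_country_id",
  "target_state_id"
)
lexicon_cols <- c("token_sequence", "position", "level_scope")
meta_cols <- c("source_name", "version", "access_date", "url", "citation_bibtex")

code_systems <- c("iso2", "iso3", "fips", "hasc")

load_error <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "poldiv_load_error")
}

read_ref_table <- function(dir, name, cols) {
  path <- file.path(dir, paste0(name, ".tsv"))
  if (!file.exists(path)) {
    load_error("reference table missing: %s", path)
  }
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), quote = "", progress = FALSE
  )
  missing <- setdiff(cols, names(tab))
  if (length(missing) > 0L) {
    load_error(
      "table %s lacks required column(s): %s", name,
      paste(missing, collapse = ", ")
    )
  }
  tab[cols]
}

#' Load a gazetteer reference world from normalized tables
#'
#' Reads the five tab-delimited reference tables from `dir`, verifies all
#' referential and hierarchy invariants, recomputes normalized strings, and
#' returns an indexed `ref_world` object used by every resolution function.
#'
#' Validation failures (missing table, dangling parent or entity reference,
#' a county whose parent is a country, duplicate codes within one scope,
#' an entity without exactly one standard-name variant) abort with a load
#' error naming the offending rows.
#'
#' @param dir Directory containing `entities.tsv`, `name_variants.tsv`,
#'   `special_cases.tsv`, `class_identifiers.tsv` and `meta.tsv`.
#' @return A `ref_world` object: list with tibbles `entities`, `variants`
#'   (the match index), `variants_raw` (file rows, for re-export),
#'   `special_cases`, `lexicon` and `meta`.
#' @seealso [generate_fixture_world()], [write_ref_world()]
#' @export
load_ref_world <- function(dir) {
  ent <- read_ref_table(dir, "entities", entity_cols)
  nv <- read_ref_table(dir, "name_variants", variant_cols)
  sc <- read_ref_table(dir, "special_cases", special_cols)
  lex <- read_ref_table(dir, "class_identifiers", lexicon_cols)
  meta <- read_ref_table(dir, "meta", meta_cols)

  validate_entities(ent)
  validate_variants(nv, ent)
  validate_special_cases(sc, ent)
  validate_lexicon(lex)

  sc$trigger_country_norm <- fold_name(sc$trigger_country)
  sc$trigger_name_norm <- fold_name(sc$trigger_name)

  variants <- build_variant_index(ent, nv)
  check_code_uniqueness(variants)

  structure(
    list(
      entities = ent,
      variants = variants,
      variants_raw = nv,
      special_cases = sc,
      lexicon = lex,
      meta = meta
    ),
    class = "ref_world"
  )
}

validate_entities <- function(ent) {
  dup <- ent$entity_id[duplicated(ent$entity_id)]
  if (length(dup) > 0L) {
    load_error("duplicate entity_id: %s", paste(unique(dup), collapse = ", "))
  }
  bad_level <- setdiff(unique(ent$level), pd_levels)
  if (length(bad_level) > 0L) {
    load_error("unknown level value(s): %s", paste(bad_level, collapse = ", "))
  }
  is_country <- ent$level == "country"
  if (any(is_country & nzchar(ent$parent_id))) {
    load_error(
      "countries must have empty parent_id: %s",
      paste(ent$entity_id[is_country & nzchar(ent$parent_id)], collapse = ", ")
    )
  }
  sub <- ent[!is_country, , drop = FALSE]
  pl <- ent$level[match(sub$parent_id, ent$entity_id)]
  dangling <- sub$entity_id[is.na(pl)]
  if (length(dangling) > 0L) {
    load_error(
      "dangling parent reference for: %s", paste(dangling, collapse = ", ")
    )
  }
  want <- ifelse(sub$level == "state_province", "country", "state_province")
  wrong <- sub$entity_id[pl != want]
  if (length(wrong) > 0L) {
    load_error(
      "parent at wrong level for: %s", paste(wrong, collapse = ", ")
    )
  }
  gid <- ent$gadm_gid[nzchar(ent$gadm_gid)]
  if (anyDuplicated(gid)) {
    load_error(
      "duplicate gadm_gid: %s", paste(unique(gid[duplicated(gid)]), collapse = ", ")
    )
  }
  ascii_ok <- !stringi::stri_detect_regex(ent$ascii_name, "[^\\x20-\\x7e]")
  if (!all(ascii_ok)) {
    load_error(
      "non-ascii ascii_name for: %s",
      paste(ent$entity_id[!ascii_ok], collapse = ", ")
    )
  }
  invisible(ent)
}

validate_variants <- function(nv, ent) {
  unknown <- setdiff(unique(nv$entity_id), ent$entity_id)
  if (length(unknown) > 0L) {
    load_error(
      "name variant for unknown entity: %s", paste(unknown, collapse = ", ")
    )
  }
  bad_class <- setdiff(
    unique(nv$variant_class), c("standard_name", "alternate_name", "code")
  )
  if (length(bad_class) > 0L) {
    load_error("unknown variant_class: %s", paste(bad_class, collapse = ", "))
  }
  is_code <- nv$variant_class == "code"
  if (any(is_code & !nv$code_system %in% code_systems)) {
    load_error("code variants must name a code_system (iso2/iso3/fips/hasc)")
  }
  if (any(!is_code & !nv$code_system %in% c("", "none"))) {
    load_error("non-code variants must have code_system 'none' or empty")
  }
  n_std <- table(nv$entity_id[nv$variant_class == "standard_name"])
  missing <- setdiff(ent$entity_id, names(n_std))
  extra <- names(n_std)[n_std > 1L]
  if (length(missing) > 0L || length(extra) > 0L) {
    load_error(
      "each entity needs exactly one standard_name variant (missing: %s; duplicated: %s)",
      paste(missing, collapse = ", "), paste(extra, collapse = ", ")
    )
  }
  invisible(nv)
}

validate_special_cases <- function(sc, ent) {
  bad_kind <- setdiff(unique(sc$kind), c("state_as_country", "country_as_state"))
  if (length(bad_kind) > 0L && nrow(sc) > 0L) {
    load_error("unknown special case kind: %s", paste(bad_kind, collapse = ", "))
  }
  lvl <- function(id) ent$level[match(id, ent$entity_id)]
  par <- function(id) ent$parent_id[match(id, ent$entity_id)]
  bad <- !is.na(sc$target_country_id) & (
    is.na(lvl(sc$target_country_id)) | lvl(sc$target_country_id) != "country"
  )
  if (any(bad)) {
    load_error("special case target_country_id must be an existing country")
  }
  has_state <- nzchar(sc$target_state_id)
  if (any(has_state)) {
    ok <- lvl(sc$target_state_id[has_state]) == "state_province" &
      par(sc$target_state_id[has_state]) == sc$target_country_id[has_state]
    if (any(is.na(ok)) || !all(ok)) {
      load_error(
        "special case target_state_id must be a state_province of target_country_id"
      )
    }
  }
  invisible(sc)
}

validate_lexicon <- function(lex) {
  if (any(!nzchar(lex$token_sequence))) {
    load_error("empty class identifier token_sequence")
  }
  if (any(lex$token_sequence != fold_name(lex$token_sequence))) {
    load_error("class identifier token sequences must be folded (lowercase ascii)")
  }
  bad_pos <- setdiff(unique(lex$position), c("prefix", "suffix", "either"))
  if (length(bad_pos) > 0L) {
    load_error("unknown lexicon position: %s", paste(bad_pos, collapse = ", "))
  }
  bad_scope <- setdiff(unique(lex$level_scope), c(pd_levels, "any"))
  if (length(bad_scope) > 0L) {
    load_error("unknown lexicon level_scope: %s", paste(bad_scope, collapse = ", "))
  }
  invisible(lex)
}

build_variant_index <- function(ent, nv) {
  name_rows <- nv[nv$variant_class != "code", , drop = FALSE]
  name_rows$code_system <- "none"
  code_rows_file <- nv[nv$variant_class == "code", c("entity_id", "text", "code_system")]

  # code variants implied by the entity code columns
  stack_codes <- function(col, system) {
    keep <- nzchar(ent[[col]])
    tibble::tibble(
      entity_id = ent$entity_id[keep], text = ent[[col]][keep],
      code_system = system
    )
  }
  code_rows <- dplyr::bind_rows(
    stack_codes("iso_alpha2", "iso2"),
    stack_codes("iso_alpha3", "iso3"),
    stack_codes("fips_code", "fips"),
    stack_codes("hasc_code", "hasc"),
    code_rows_file
  )
  code_rows$variant_class <- "code"
  code_rows$language <- ""

  v <- dplyr::bind_rows(
    name_rows[c("entity_id", "text", "variant_class", "code_system", "language")],
    code_rows[c("entity_id", "text", "variant_class", "code_system", "language")]
  )
  v$text_norm <- fold_name(v$text)
  v <- dplyr::distinct(
    v, .data$entity_id, .data$variant_class, .data$code_system, .data$text_norm,
    .keep_all = TRUE
  )
  idx <- match(v$entity_id, ent$entity_id)
  v$level <- ent$level[idx]
  v$parent_id <- ent$parent_id[idx]
  v$standard_name <- ent$standard_name[idx]
  is_name <- v$variant_class != "code"
  v$grams <- vector("list", nrow(v))
  v$grams[is_name] <- lapply(v$text_norm[is_name], name_trigrams)
  v
}

check_code_uniqueness <- function(variants) {
  cv <- variants[variants$variant_class == "code", , drop = FALSE]
  key <- paste(cv$level, cv$parent_id, cv$code_system, cv$text_norm, sep = "\x1f")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    load_error(
      "ambiguous code within one scope: %s",
      paste(unique(paste0(
        cv$code_system[dup], "=", cv$text_norm[dup], " (", cv$entity_id[dup], ")"
      )), collapse = ", ")
    )
  }
  invisible(variants)
}

#' @export
print.ref_world <- function(x, ...) {
  n_lvl <- table(factor(x$entities$level, levels = pd_levels))
  cat(
    "<ref_world> ", nrow(x$entities), " entities (",
    paste0(n_lvl, " ", names(n_lvl), collapse = ", "), "), ",
    nrow(x$variants), " indexed variants, ",
    nrow(x$special_cases), " special cases\n",
    sep = ""
  )
  invisible(x)
}

#' Re-export a reference world to normalized tables
#'
#' Writes the five reference tables back to `dir` in the same schema the
#' loader reads, so that generate/load/re-export round trips preserve row
#' multisets.
#'
#' @param world A `ref_world`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ref_world <- function(world, dir) {
  stopifnot(inherits(world, "ref_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_one <- function(tab, cols, name) {
    readr::write_tsv(tab[cols], file.path(dir, paste0(name, ".tsv")),
      na = "", quote = "none", escape = "none", progress = FALSE
    )
  }
  write_one(world$entities, entity_cols, "entities")
  write_one(world$variants_raw, variant_cols, "name_variants")
  write_one(world$special_cases, special_cols, "special_cases")
  write_one(world$lexicon, lexicon_cols, "class_identifiers")
  write_one(world$meta, meta_cols, "meta")
  invisible(dir)
}

entity_by_id <- function(world, id) {
  world$entities[match(id, world$entities$entity_id), , drop = FALSE]
}

# Variant rows matching a code in one scope, ordered by code-system priority
# (iso2, iso3, fips, hasc) then entity_id.
lookup_code_variants <- function(world, level, scope, code_norm) {
  v <- world$variants
  hit <- v[
    v$variant_class == "code" & v$level == level &
      v$parent_id == scope & v$text_norm == code_norm, ,
    drop = FALSE
  ]
  if (nrow(hit) == 0L) {
    return(hit)
  }
  hit[order(match(hit$code_system, code_systems), hit$entity_id), , drop = FALSE]
}

#' Look up entities by code
#'
#' Finds entities at `level` within `scope` having any code variant (ISO
#' alpha-2/alpha-3, FIPS or HASC) whose folded form equals `code_norm`.
#' Codes are matched exactly (never fuzzily) and case-insensitively after
#' folding, so the HASC form `"US.AZ"` is queried as `fold_name("US.AZ")`.
#'
#' @param world A `ref_world`.
#' @param level Target level.
#' @param scope `entity_id` of the containing division (`""` for countries).
#' @param code_norm Folded code string.
#' @return Tibble of matching entity rows ordered by code-system priority
#'   (iso2, iso3, fips, hasc) then `entity_id`; zero rows when absent.
#' @export
lookup_code <- function(world, level, scope = "", code_norm) {
  level <- rlang::arg_match(level, pd_levels)
  hit <- lookup_code_variants(world, level, scope, code_norm)
  entity_by_id(world, unique(hit$entity_id))
}

#' Look up entities by exact name
#'
#' Finds entities at `level` within `scope` having a name variant of class
#' `variant_class` whose folded form equals `name_norm`.
#'
#' @inheritParams lookup_code
#' @param name_norm Folded (and, query-side, class-identifier-stripped) name.
#' @param variant_class `"standard_name"` or `"alternate_name"`.
#' @return Tibble of matching entity rows ordered by `entity_id`.
#' @export
lookup_name <- function(world, level, scope = "", name_norm,
                        variant_class = c("standard_name", "alternate_name")) {
  level <- rlang::arg_match(level, pd_levels)
  variant_class <- rlang::arg_match(variant_class)
  v <- world$variants
  hit <- v[
    v$variant_class == variant_class & v$level == level &
      v$parent_id == scope & v$text_norm == name_norm, ,
    drop = FALSE
  ]
  entity_by_id(world, sort(unique(hit$entity_id)))
}

#' List child divisions of an entity
#'
#' @inheritParams lookup_code
#' @param parent `entity_id` of the parent division, or `""` to list
#'   countries.
#' @return Tibble of entity rows at `level` under `parent`, sorted by
#'   `standard_name` then `entity_id`.
#' @export
list_children <- function(world, parent = "", level) {
  level <- rlang::arg_match(level, pd_levels)
  if (nzchar(parent)) {
    pl <- world$entities$level[match(parent, world$entities$entity_id)]
    if (is.na(pl)) {
      rlang::abort(paste0("unknown parent entity: ", parent),
        class = "poldiv_lookup_error"
      )
    }
    want <- c(state_province = "country", county_parish = "state_province")[level]
    if (is.na(want) || pl != want) {
      rlang::abort("parent must be exactly one level above the requested level",
        class = "poldiv_lookup_error"
      )
    }
  } else if (level != "country") {
    rlang::abort("empty parent is only valid when listing countries",
      class = "poldiv_lookup_error"
    )
  }
  ent <- world$entities
  out <- ent[ent$level == level & ent$parent_id == parent, , drop = FALSE]
  out[order(out$standard_name, out$entity_id), , drop = FALSE]
}
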