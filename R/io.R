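# Input/output formats: delimited PDC input files, CSV/TSV/JSON result
# serialization, the data dictionary, and the JSON request payload contract.

#' Input dialects for PDC files
#'
#' `web3col` lines have exactly 3 comma-separated fields
#' (country,state_province,county_parish); `api4col` lines have exactly 4,
#' with a leading (possibly empty) `user_id`. Fields containing commas must
#' be wrapped in double quotes.
#' @keywords internal
#' @name input-dialects
NULL

pd_dialects <- c("web3col", "api4col")

split_csv_line <- function(line) {
  if (!nzchar(line)) {
    return(character(0))
  }
  scan(
    text = line, what = character(), sep = ",", quote = "\"",
    quiet = TRUE, blank.lines.skip = FALSE, strip.white = FALSE
  )
}

#' Parse political division combinations from delimited text
#'
#' Splits `text` into lines and parses each as a quoted-comma-delimited PDC
#' row in the given dialect. In strict mode rows with the wrong delimiter
#' count are rejected with a diagnostic; in lenient mode (the default) rows
#' with too few fields are padded with trailing empties and a warning
#' diagnostic is recorded. Rows with too many fields are always rejected.
#' A county without a state is demoted to unused with a warning. Every
#' input line is accounted for: it yields a parsed PDC, an error
#' diagnostic, or both a PDC and a warning.
#'
#' @param text Character scalar (or vector of lines) of UTF-8 input.
#' @param dialect `"web3col"` or `"api4col"`.
#' @param strict Reject rather than pad short rows.
#' @return List with `pdcs` (tibble: `line`, `user_id`, `country`,
#'   `state_province`, `county_parish`) and `diagnostics` (tibble: `line`,
#'   `severity` (`"warning"`/`"error"`), `message`).
#' @examples
#' parse_pdc_lines("USA,Arizona,Pima County")$pdcs
#' @export
parse_pdc_lines <- function(text, dialect = c("web3col", "api4col"),
                            strict = FALSE) {
  dialect <- rlang::arg_match(dialect)
  expected <- if (dialect == "web3col") 3L else 4L
  lines <- if (length(text) == 1L) {
    stringi::stri_split_lines(text, omit_empty = FALSE)[[1]]
  } else {
    as.character(text)
  }
  # a trailing newline does not constitute an empty final record
  if (length(lines) > 0L && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  bad_utf8 <- which(!validUTF8(lines))
  if (length(bad_utf8) > 0L) {
    rlang::abort(
      sprintf("undecodable (non-UTF-8) bytes on line %d", bad_utf8[1L]),
      class = "poldiv_input_error"
    )
  }

  pdc_rows <- list()
  diags <- list()
  add_diag <- function(line, severity, message) {
    diags[[length(diags) + 1L]] <<- tibble::tibble(
      line = line, severity = severity, message = message
    )
  }
  for (i in seq_along(lines)) {
    fields <- split_csv_line(lines[i])
    n <- length(fields)
    if (n > expected) {
      add_diag(i, "error", sprintf(
        "expected %d delimiter(s), found %d field(s)", expected - 1L, n
      ))
      next
    }
    if (n < expected) {
      if (strict) {
        add_diag(i, "error", sprintf(
          "expected %d delimiter(s), found %d field(s)", expected - 1L, n
        ))
        next
      }
      add_diag(i, "warning", sprintf(
        "padded %d missing trailing field(s)", expected - n
      ))
      fields <- c(fields, rep("", expected - n))
    }
    fields <- stringr::str_trim(fields)
    if (dialect == "api4col") {
      user_id <- fields[1L]
      fields <- fields[-1L]
    } else {
      user_id <- ""
    }
    if (nzchar(fields[3L]) && !nzchar(fields[2L])) {
      add_diag(i, "warning", "county_parish ignored: no state_province submitted")
      fields[3L] <- ""
    }
    pdc_rows[[length(pdc_rows) + 1L]] <- tibble::tibble(
      line = i, user_id = user_id, country = fields[1L],
      state_province = fields[2L], county_parish = fields[3L]
    )
  }
  empty_pdcs <- tibble::tibble(
    line = integer(0), user_id = character(0), country = character(0),
    state_province = character(0), county_parish = character(0)
  )
  empty_diags <- tibble::tibble(
    line = integer(0), severity = character(0), message = character(0)
  )
  list(
    pdcs = if (length(pdc_rows)) dplyr::bind_rows(pdc_rows) else empty_pdcs,
    diagnostics = if (length(diags)) dplyr::bind_rows(diags) else empty_diags
  )
}

#' Read a PDC input file
#'
#' @param path File of one PDC per line.
#' @inheritParams parse_pdc_lines
#' @return As [parse_pdc_lines()].
#' @export
read_pdc_file <- function(path, dialect = c("web3col", "api4col"),
                          strict = FALSE) {
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  txt <- rawToChar(raw)
  Encoding(txt) <- "UTF-8"
  parse_pdc_lines(txt, dialect = dialect, strict = strict)
}

pd_score_fields <- c(
  "match_score_country", "match_score_state_province",
  "match_score_county_parish", "overall_score"
)

#' The resolution output data dictionary
#'
#' One entry per field of a resolution result row, in output order.
#'
#' @return Tibble with `field_name`, `definition`, `value_domain`.
#' @export
data_dictionary <- function() {
  tibble::tribble(
    ~field_name, ~definition, ~value_domain,
    "user_id", "User-supplied record identifier, echoed verbatim", "free text; may be empty",
    "country_verbatim", "Country as submitted", "free text",
    "state_province_verbatim", "State/province as submitted", "free text; may be empty",
    "county_parish_verbatim", "County/parish as submitted", "free text; may be empty",
    "country", "Matched standard country name", "gazetteer standard name or empty",
    "state_province", "Matched standard state/province name", "gazetteer standard name or empty",
    "county_parish", "Matched standard county/parish name", "gazetteer standard name or empty",
    "country_ascii", "Plain-ascii country name minus class identifiers", "ascii text or empty",
    "state_province_ascii", "Plain-ascii state/province name minus class identifiers", "ascii text or empty",
    "county_parish_ascii", "Plain-ascii county/parish name minus class identifiers", "ascii text or empty",
    "country_iso2", "ISO 3166-1 alpha-2 code of the matched country", "2-letter code or empty",
    "country_iso3", "ISO 3166-1 alpha-3 code of the matched country", "3-letter code or empty",
    "state_province_hasc", "HASC code of the matched state/province", "e.g. US.AZ; may be empty",
    "county_parish_hasc", "HASC code of the matched county/parish", "e.g. US.AZ.PM; may be empty",
    "country_geoname_id", "Gazetteer identifier of the matched country", "integer or empty",
    "state_province_geoname_id", "Gazetteer identifier of the matched state/province", "integer or empty",
    "county_parish_geoname_id", "Gazetteer identifier of the matched county/parish", "integer or empty",
    "gid_0", "Spatial object identifier of the matched country", "gid_0-style string or empty",
    "gid_1", "Spatial object identifier of the matched state/province", "gid_1-style string or empty",
    "gid_2", "Spatial object identifier of the matched county/parish", "gid_2-style string or empty",
    "match_method_country", "How the country was matched", "iso code|fips code|hasc code|exact match standard name|exact match alternate name|fuzzy match standard name|fuzzy match alternate name|state as country|country as state|empty",
    "match_method_state_province", "How the state/province was matched", "as match_method_country",
    "match_method_county_parish", "How the county/parish was matched", "as match_method_country",
    "match_score_country", "Trigram similarity of submitted vs matched country name", "[0,1]; 1 = exact",
    "match_score_state_province", "Trigram similarity of submitted vs matched state name", "[0,1]; 1 = exact",
    "match_score_county_parish", "Trigram similarity of submitted vs matched county name", "[0,1]; 1 = exact",
    "overall_score", "Mean per-level match score over submitted levels", "[0,1]",
    "match_status", "Overall match completeness", "no match|partial match|full match",
    "poldiv_submitted", "Deepest non-empty submitted level", "country|state_province|county_parish",
    "poldiv_matched", "Deepest matched level", "country|state_province|county_parish|empty",
    "note", "Per-record processing notes", "free text; may be empty"
  )
}

#' Serialize resolution results
#'
#' Writes results as CSV (RFC-4180 quoting), TSV (no quoting; tabs in
#' fields are an error) or JSON (array of objects keyed by data-dictionary
#' field names). Scores are rendered with 4 decimal places.
#'
#' @param results A `pd_results` tibble (or compatible data frame).
#' @param format `"csv"`, `"tsv"` or `"json"`.
#' @return A single string of serialized output.
#' @export
write_results <- function(results, format = c("csv", "tsv", "json")) {
  format <- rlang::arg_match(format)
  fields <- data_dictionary()$field_name
  stopifnot(all(fields %in% names(results)))
  out <- results[fields]
  if (format == "json") {
    for (f in pd_score_fields) out[[f]] <- round(out[[f]], 4)
    return(as.character(jsonlite::toJSON(
      out,
      dataframe = "rows", na = "null", digits = NA
    )))
  }
  for (f in pd_score_fields) out[[f]] <- sprintf("%.4f", out[[f]])
  if (format == "csv") {
    readr::format_csv(out, na = "")
  } else {
    has_tab <- vapply(
      out, function(x) any(stringi::stri_detect_fixed(x, "\t")), logical(1)
    )
    if (any(has_tab)) {
      rlang::abort("tab characters are not allowed in TSV fields",
        class = "poldiv_output_error"
      )
    }
    readr::format_tsv(out, na = "")
  }
}

pd_endpoints <- c(
  "resolve", "countrylist", "statelist", "countylist", "meta", "sources",
  "citations", "dd"
)

#' Build a JSON request payload
#'
#' Mirrors the service request contract: options under `"opts"` (the
#' endpoint in `mode`, plus an optional `tfuzzy` for `resolve`) and rows
#' under `"data"`.
#'
#' @param mode Endpoint name (see [parse_request()]).
#' @param data Optional rows: for `resolve`, a data frame or list of
#'   4-element `(user_id, country, state_province, county_parish)` rows;
#'   for `statelist`/`countylist`, a vector of country names / state ids.
#' @param tfuzzy Optional fuzzy threshold (resolve only).
#' @return JSON string.
#' @export
build_request <- function(mode, data = NULL, tfuzzy = NULL) {
  mode <- rlang::arg_match(mode, pd_endpoints)
  opts <- list(mode = mode)
  if (!is.null(tfuzzy)) opts$tfuzzy <- tfuzzy
  payload <- list(opts = opts)
  if (!is.null(data)) {
    if (is.data.frame(data)) {
      cols <- c("user_id", "country", "state_province", "county_parish")
      for (nm in cols) if (!nm %in% names(data)) data[[nm]] <- ""
      data <- lapply(seq_len(nrow(data)), function(i) {
        as.character(unlist(data[i, cols], use.names = FALSE))
      })
    }
    payload$data <- data
  }
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA))
}

#' Parse and validate a JSON request payload
#'
#' Accepts a payload with `"opts"` (endpoint in `mode`, optional `tfuzzy`
#' in `[0, 1]` for `resolve`) and optional `"data"` rows following the
#' 4-column `api4col` semantics. Requests exceeding `batch_cap` rows
#' (default 5000) are rejected.
#'
#' @param payload JSON string or an already-parsed list.
#' @param batch_cap Maximum number of data rows accepted per request.
#' @return List with `endpoint`, `params` (currently `tfuzzy`) and `data`
#'   (tibble of PDCs for `resolve`; character vector for the list
#'   endpoints; `NULL` otherwise).
#' @export
parse_request <- function(payload, batch_cap = 5000L) {
  if (is.character(payload)) {
    payload <- tryCatch(
      jsonlite::fromJSON(payload, simplifyVector = FALSE),
      error = function(e) {
        rlang::abort(paste0("malformed JSON request: ", conditionMessage(e)),
          class = "poldiv_request_error"
        )
      }
    )
  }
  if (!is.list(payload) || is.null(payload$opts) || is.null(payload$opts$mode)) {
    rlang::abort("request must carry opts.mode", class = "poldiv_request_error")
  }
  mode <- as.character(payload$opts$mode)
  if (!mode %in% pd_endpoints) {
    rlang::abort(paste0("unknown endpoint: ", mode),
      class = "poldiv_request_error"
    )
  }
  tfuzzy <- NULL
  if (mode == "resolve" && !is.null(payload$opts$tfuzzy)) {
    tfuzzy <- suppressWarnings(as.numeric(payload$opts$tfuzzy))
    if (length(tfuzzy) != 1L || is.na(tfuzzy) || tfuzzy < 0 || tfuzzy > 1) {
      rlang::abort("tfuzzy must be a number in [0, 1]",
        class = "poldiv_request_error"
      )
    }
  }
  data <- payload$data
  parsed_data <- NULL
  if (mode == "resolve") {
    data <- data %||% list()
    if (length(data) > batch_cap) {
      rlang::abort(
        sprintf(
          "request has %d rows; the per-request limit is %d",
          length(data), batch_cap
        ),
        class = "poldiv_cap_error"
      )
    }
    rows <- lapply(seq_along(data), function(i) {
      f <- as.character(unlist(data[[i]], use.names = FALSE))
      if (length(f) > 4L) {
        rlang::abort(
          sprintf("data row %d has %d fields; expected 4", i, length(f)),
          class = "poldiv_request_error"
        )
      }
      c(f, rep("", 4L - length(f)))
    })
    parsed_data <- tibble::tibble(
      user_id = vapply(rows, `[`, "", 1L),
      country = vapply(rows, `[`, "", 2L),
      state_province = vapply(rows, `[`, "", 3L),
      county_parish = vapply(rows, `[`, "", 4L)
    )
  } else if (mode %in% c("statelist", "countylist")) {
    parsed_data <- as.character(unlist(data %||% list(), use.names = FALSE))
  }
  list(endpoint = mode, params = list(tfuzzy = tfuzzy), data = parsed_data)
}

entity_listing <- function(ent, level) {
  id_col <- paste0(
    c(
      country = "country", state_province = "state_province",
      county_parish = "county_parish"
    )[[level]], "_id"
  )
  out <- tibble::tibble(
    name = ent$standard_name,
    ascii_name = ent$ascii_name,
    iso_alpha2 = ent$iso_alpha2,
    iso_alpha3 = ent$iso_alpha3,
    hasc_code = ent$hasc_code,
    geoname_id = ent$geoname_id,
    gadm_gid = ent$gadm_gid
  )
  out[[id_col]] <- ent$entity_id
  out
}

#' Handle one JSON request against a loaded world
#'
#' Parses, dispatches and serializes a full request/response cycle: the
#' JSON analog of the command line subcommands. Errors (malformed JSON,
#' unknown endpoint, cap exceeded) are returned as an `{"error": ...}`
#' payload rather than raised.
#'
#' @param world A `ref_world`.
#' @param payload JSON string or parsed list (see [parse_request()]).
#' @param batch_cap Row cap for `resolve` requests.
#' @param default_tfuzzy Threshold used when the request does not set one.
#' @return JSON string response.
#' @export
handle_request <- function(world, payload, batch_cap = 5000L,
                           default_tfuzzy = 0.5) {
  req <- tryCatch(parse_request(payload, batch_cap = batch_cap),
    error = function(e) e
  )
  if (inherits(req, "error")) {
    return(as.character(jsonlite::toJSON(
      list(error = conditionMessage(req)),
      auto_unbox = TRUE
    )))
  }
  tojson <- function(x) {
    as.character(jsonlite::toJSON(x, dataframe = "rows", na = "null", digits = NA))
  }
  tryCatch(switch(req$endpoint,
    resolve = {
      res <- resolve_political_divisions(
        req$data, world,
        tfuzzy = req$params$tfuzzy %||% default_tfuzzy
      )
      write_results(res, "json")
    },
    countrylist = tojson(
      entity_listing(list_children(world, "", "country"), "country")
    ),
    statelist = {
      out <- lapply(req$data, function(nm) {
        ent <- lookup_name(world, "country", "", fold_name(nm), "standard_name")
        if (nrow(ent) == 0L) {
          return(NULL)
        }
        entity_listing(
          list_children(world, ent$entity_id[1L], "state_province"),
          "state_province"
        )
      })
      tojson(dplyr::bind_rows(out))
    },
    countylist = {
      out <- lapply(req$data, function(id) {
        entity_listing(
          list_children(world, id, "county_parish"), "county_parish"
        )
      })
      tojson(dplyr::bind_rows(out))
    },
    meta = tojson(world$meta[world$meta$source_name == "poldiv", ]),
    sources = tojson(world$meta[world$meta$source_name != "poldiv", ]),
    citations = tojson(world$meta[c("source_name", "citation_bibtex")]),
    dd = tojson(data_dictionary())
  ), error = function(e) {
    as.character(jsonlite::toJSON(
      list(error = conditionMessage(e)),
      auto_unbox = TRUE
    ))
  })
}
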