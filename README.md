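# poldiv

Batch standardization of political division names against a gazetteer.

## The problem

Species occurrence records — and any other data aggregated by
administrative units — declare where an observation was made as a 1–3
level *political division combination* (PDC): country, optionally
state/province, optionally county/parish. Before coordinates can be
validated against boundary polygons, or records joined across sources,
those declared names have to be resolved to one reference representation.
In real data they arrive as alternative spellings, abbreviations, ISO/
FIPS/HASC codes, names in several languages, accented and plain forms,
typos, and names wrapped in division-type words ("Provincia de …",
"… County"). poldiv is for data curators and biodiversity informaticians
who need to resolve such batches reproducibly: it returns standardized
names, plain-ascii names, codes, gazetteer identifiers and spatial-object
identifiers (`gid_0`/`gid_1`/`gid_2`), plus per-level match methods and
scores, an overall score and a match status for every input row.

## How matching works

Each PDC is resolved top-down (country → state → county); a level is only
searched within its matched parent, and a failed level stops descent. At
one level the cascade is, in strict order: code lookup (ISO alpha-2/alpha-3,
FIPS, HASC) → exact standard name → exact alternate name → fuzzy standard
name → fuzzy alternate name; the first stage with a hit wins, so an exact
match can never be shadowed by a fuzzy one. Names are compared after
folding (unicode decomposition, lowercase, punctuation → space) and
removal of division-type class identifiers. Fuzzy matching scores a
candidate pair by the Jaccard coefficient of padded character trigram
sets,

    sim(a, b) = |T(a) ∩ T(b)| / |T(a) ∪ T(b)|,

where every word is padded with two leading spaces and one trailing space
before the 3-character windows are taken (the convention of the PostgreSQL
trigram module). Candidates are accepted when `sim` reaches the threshold
`tfuzzy`, default **0.5** — conservative on purpose: a false positive is
worse than a miss. The `overall_score` of a record is the mean per-level
score over its submitted levels; `match_status` is "full match" /
"partial match" / "no match". Two special-case passes remap territories
recorded as states of their administering country ("USA, Puerto Rico" →
the Puerto Rico entity) and member countries of multinational unions
recorded as countries ("England" → United Kingdom + England).

## Worked example

Reference data come from any warehouse that writes the five documented TSV
tables; for demos and tests the package generates a deterministic
synthetic mini-gazetteer:

```r
library(poldiv)

d <- file.path(tempdir(), "demo-world")
generate_fixture_world(d, seed = 1, n_extra = 0)
world <- load_ref_world(d)

pdcs <- tibble::tibble(
  country        = c("USA",         "México", "Costa Rica", "Mexiico"),
  state_province = c("Arizona",     "Oaxaca", "",           ""),
  county_parish  = c("Pima County", "",       "",           "")
)
res <- resolve_political_divisions(pdcs, world)
res[, c("country", "state_province", "county_parish",
        "match_method_country", "match_score_country",
        "overall_score", "match_status")]
#>         country state_province county_parish      match_method_country
#> 1 United States        Arizona          Pima                  iso code
#> 2        México         Oaxaca               exact match standard name
#> 3    Costa Rica                              exact match standard name
#> 4        México                              fuzzy match standard name
#>   match_score_country overall_score match_status
#> 1           1.0000000     1.0000000   full match
#> 2           1.0000000     1.0000000   full match
#> 3           1.0000000     1.0000000   full match
#> 4           0.6666667     0.6666667   full match
```

Row 1 shows the cascade at work: "USA" matched the United States by ISO
code, "Arizona" and "Pima County" matched standard names exactly (the
"County" class identifier is stripped before matching), so every level
scores 1 and the record is a full match. Row 4 is a one-typo country:
"Mexiico" matched "México" fuzzily with trigram similarity 0.667 ≥ 0.5.
A batch summary is one call away:

```r
glance(res)
#>   n n_full n_partial n_no_match pct_full pct_partial pct_no_match ...
#> 1 4      4         0          0      100           0            0
```

`tidy(res)` gives a per-level long view, `autoplot(res)` a status bar
chart. The same resolution is available from the shell
(`exec/poldiv resolve --refdb DIR --input pdcs.csv --format csv`, with no
row cap) and as a JSON request contract (`handle_request()`, default cap
5,000 rows per request, optional `tfuzzy` parameter), along with listing
and metadata endpoints (`countrylist`, `statelist`, `countylist`, `meta`,
`sources`, `citations`, `dd`).

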