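---
title: "Resolving political division names against a gazetteer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving political division names against a gazetteer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poldiv)
library(tibble)
```

## The problem

Species occurrence records, public-health tables and many other datasets
declare *where* an observation was made as a 1–3 level political division
combination (PDC): a country, optionally a first-level division
(state/province/department) and optionally a second-level division
(county/parish/municipality). Before such records can be validated against
administrative boundary polygons or joined across sources, the declared
names must be resolved to a single reference representation. That is hard
in practice because the same division appears under alternative spellings,
abbreviations, codes (ISO 3166, FIPS, HASC), multiple languages, accented
and unaccented forms, and with attached division-type words ("State of",
"Provincia de", "Oblast", "County"). poldiv standardizes batches of PDCs
against a gazetteer and returns, per record, the standard names, plain-ascii
names, codes, gazetteer and spatial-object identifiers, how each level was
matched, a per-level and an overall match score, and an overall match
status.

Unlike free-text toponym resolution, the input here is structured: each
field is already known to be an administrative division at a known rank.
poldiv therefore never guesses entity types, and it exploits the hierarchy
aggressively — a state is only searched within its matched country and a
county only within its matched state. Hierarchical scoping is the central
disambiguation device: thousands of county names are ambiguous globally but
nearly unique within one state.

## The reference data model

A `ref_world` holds four user-visible tables (plus source metadata):

* **entities** — one row per division with `level`, a parent link,
  the standard name, a plain-ascii name with class identifiers removed,
  ISO alpha-2/alpha-3, FIPS and HASC codes where available, a gazetteer
  identifier (`geoname_id`) and a spatial-object identifier
  (`gadm_gid`, `gid_0`/`gid_1`/`gid_2` style).
* **name_variants** — every matchable string: exactly one standard name
  per entity, any number of alternate names with language tags, and code
  variants (e.g. ISO-3166-2-style subdivision codes).
* **special_cases** — remapping rules for two well-known pathologies of
  declared localities, described below.
* **class_identifiers** — the lexicon of division-type words and
  abbreviations stripped from queries before matching, each with a
  permitted position (prefix/suffix/either) and a level scope.

The loader (`load_ref_world()`) recomputes every normalized string itself
and verifies referential integrity (parent levels, unique identifiers,
exactly one standard name per entity, unambiguous codes within one scope);
violations are fatal at load time so the resolver can assume a consistent
world. The on-disk format is five plain TSV tables, which keeps reference
data diffable and lets any upstream warehouse produce them.

## Normalization and the trigram metric

All comparisons happen on *folded* strings: unicode compatibility
decomposition, combining marks removed, lowercased, every character outside
`[a-z0-9]` mapped to a single space, whitespace collapsed ("México" →
"mexico", "Yakarinta—Wowetta, Surama" → "yakarinta wowetta surama"). A
single punctuation rule — everything non-alphanumeric becomes a space — is
deliberate: it needs no dialect tables and handles hyphens, em-dashes,
apostrophes and commas uniformly. Digits are kept because some districts
are numbered. Codes go through the same fold, so the HASC form `US.AZ` is
indexed and queried as `us az`; since both sides use the same rule, whole-
string code matching is unaffected.

Queries are additionally *stripped* of class identifiers before exact name
lookup and fuzzy candidate selection ("Pima County" → "pima";
"Provincia de Oaxaca" → "oaxaca"). At most one prefix and one suffix
sequence are removed, longest match first, and removal that would empty the
string is refused so a bare "County" stays matchable. Reference-side ascii
names are expected to arrive already stripped — that is a property of the
warehouse that builds the tables, mirrored by query-side stripping.

Fuzzy matching uses the Jaccard coefficient of padded character trigram
sets. Each word is padded with two leading spaces and one trailing space,
all 3-character windows are collected, and

$$\mathrm{sim}(a, b) \;=\; \frac{|T(a) \cap T(b)|}{|T(a) \cup T(b)|},$$

defined as 1 when both sets are empty and 0 when exactly one is. This is
the trigram convention used by the widely deployed PostgreSQL trigram
module, and the default acceptance threshold of **0.5** was chosen to suit
it: a conservative setting that favors avoiding false positives over
recovering every typo. The threshold (`tfuzzy`) applies uniformly at all
three levels and can be set per call or per request.

```{r}
trigram_similarity("arizona", "arizonna") # 7 shared grams of 10 distinct
```

## The matching cascade

Each level is resolved by the first stage that produces a hit, in strict
order:

1. **code lookup** on the folded input (ISO alpha-2, alpha-3, FIPS, HASC —
   reported as "iso code", "fips code" or "hasc code");
2. **exact standard name** on the stripped input;
3. **exact alternate name** on the stripped input;
4. **fuzzy over standard names**;
5. **fuzzy over alternate names**.

Exact stages score 1. Fuzzy stages admit only candidates whose similarity
to the stripped query reaches the threshold; the reported score is the
similarity between the *folded, unstripped* submitted name and the folded
matched variant, so the score reflects what the user actually typed. Codes
are never matched fuzzily — near-miss codes collide far too easily to be
worth it. Ties are broken deterministically: higher similarity first (fuzzy
only), then standard-name candidates over alternate-name candidates (built
into the stage order), then lexicographic standard name, then entity
identifier.

Levels are resolved top-down, and a failed level stops descent: when the
state cannot be matched, the county is not attempted at all, because
cross-country or cross-state matching would reintroduce exactly the
ambiguity the hierarchy removes. Unattempted and unmatched levels carry an
empty method and a score of 0.

### Scores and status

The `overall_score` is the arithmetic mean of the per-level scores over the
*submitted* levels, so `("USA", "Narnia", "Pima County")` scores
$(1 + 0 + 0)/3 \approx 0.333$: the record is penalized for every level it
claimed but could not support. `match_status` is "full match" when every
submitted level matched, "no match" when none did, and "partial match"
otherwise. The deepest submitted and deepest matched levels are reported
separately so downstream filters can require, say, county-level resolution.

### Special cases

Two systematic pathologies of declared localities get explicit handling:

* **States as countries.** Territories such as Puerto Rico are top-level
  entities in the gazetteer but are routinely recorded as
  `"USA", "Puerto Rico"`. When the submitted state fails to resolve under
  the matched country and its folded form exactly equals a trigger, the
  record is remapped to the territory's own country entity (method
  "state as country", score 1); a submitted county is then re-resolved as
  a first-level division of the new country.
* **Countries as states.** Member countries of multinational unions —
  England, Scotland — are first-level divisions in the gazetteer but appear
  as countries in data. A trigger on the submitted country fills both the
  country (the union) and the state (the member), and a submitted state
  shifts down to the county position.

Triggers match exactly after folding, never fuzzily: a false remap is far
worse than a miss. After a remap, the overall score and status are computed
over the *populated output slots* — the levels that actually carry a
(possibly shifted) submitted name. This choice keeps the two motivating
examples clean: `"USA", "Puerto Rico"` is a full match with score 1 (the
submitted state *was* matched, at country level), and a bare `"England"`
fills two output levels from one submitted field without diluting the
score. When a remap shifts names down and the bottom level falls off the
three-level hierarchy, the dropped field is noted in the record's `note`.

### Batches, caching, determinism

`resolve_political_divisions()` takes a data frame, resolves each distinct
normalized `(country, state, county, tfuzzy)` key once, and reuses the
result for duplicates — occurrence datasets are dominated by repeated PDCs,
so this is the single most important performance feature. The cache key
includes the threshold because results depend on it; verbatim strings and
`user_id` are filled per row, which is sound because every computed field
depends only on the folded inputs. Resolution is fully deterministic for a
fixed world, input and threshold; cache and chunking provably do not change
results (tested by comparing runs).

Invalid rows never abort a batch: a missing country yields a "no match" row
with an explanatory note, and a county without a state is demoted with a
note, mirroring the parser's behavior for delimited input.

## The synthetic gazetteer

`generate_fixture_world()` writes a deterministic mini-gazetteer used by
the test suite, the worked examples and the acceptance script. The curated
core covers the situations the resolver must handle: an accented standard
name (México), a hyphenated multi-word division, a county name containing
a comma and an em-dash, alternate names in three languages, codes in all
four systems, a class-identifier lexicon including abbreviations, and both
special-case kinds (a Puerto Rico analog and a United Kingdom analog with
England and Scotland). Real ISO codes are reused for recognizability only;
no claim of completeness or currency is made, which keeps tests independent
of gazetteer versions. Seeded random extras (syllable-generated names,
6–15 characters, 0–3 alternate names each, plausible unique codes) scale
the world up; output is byte-identical for a fixed `(seed, n_extra)`.

What the fixture deliberately does **not** emulate: the sheer size of a
real gazetteer (hundreds of thousands of divisions), the density of
near-duplicate names within one scope, non-Latin scripts needing
transliteration, historical entities, and administrative levels below the
county. Passing tests therefore demonstrate the correctness of the
matching logic, not recall on any particular real-world corpus.

## Validation design and problem sizes

The suite favors property-style checks over examples: the trigram metric is
compared exactly against an independently coded brute-force oracle on 1,000
seeded random string pairs; cascade precedence is checked by resolving
every stored variant and asserting an exact method; threshold monotonicity
is checked across {0.3, 0.5, 0.7, 0.9}; and a seeded corpus of 200
single-edit perturbations of fixture names measures recovery at the default
threshold (fixture world: curated core plus 40 random divisions). These
sizes run in well under a minute on one CPU and were chosen as the smallest
corpora that exercise every code path with stable statistics.

One recovery limit is worth stating plainly, because it is a property of
the metric, not a defect of the implementation: for a one-word name of
length $L$, a mid-word substitution leaves $L-2$ of the $L+1$ padded
trigrams intact, giving similarity $(L-2)/(L+4)$, which is below 0.5
whenever $L < 8$. Single-character typos in very short names ("Pima",
"Guyana", "Oaxaca") therefore frequently fall below the conservative
default threshold and are reported as no-match rather than risk a false
positive. Raising recall for short names means lowering `tfuzzy`, with the
usual precision trade-off.

## Interfaces

Everything is callable from R; the same operations are exposed as JSON
requests (`handle_request()`, with a 5,000-row per-request default cap and
an optional `tfuzzy` parameter) and as shell subcommands via `exec/poldiv`
(`resolve`, `countrylist`, `statelist`, `countylist`, `meta`, `sources`,
`citations`, `dd`, `build-fixtures`, `load-check`, `serve`). Command-line
resolution streams arbitrarily large files in chunks and applies no row
cap; the cap protects only the request/response service, whose minimal
single-threaded implementation (`serve()`) is intended for local pipeline
use. Delimited input follows the documented 3-column web and 4-column
API dialects, with RFC-4180 quoting for names containing commas; a strict
mode enforces the delimiter-count rule exactly, while the default lenient
mode pads short rows and records a diagnostic.

## Known limitations

* Resolution stops at the third administrative level.
* Only modern divisions: historical entities and boundary changes are out
  of scope, as is any geometry handling — the output identifiers are meant
  to be joined to boundary data downstream.
* Transliteration beyond unicode decomposition is not attempted, so
  non-Latin-script names match only via stored alternate names.
* Fuzzy matching is name-based only; there is no phonetic or
  token-reordering similarity.
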