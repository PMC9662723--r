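test_that("the cascade prefers codes, then exact names, then fuzzy", {
  world <- fixture_world()

  m <- resolve_level(world, "country", "", "USA")
  expect_identical(m$entity$standard_name, "United States")
  expect_identical(m$method, "iso code")
  expect_identical(m$score, 1)

  m <- resolve_level(world, "country", "", "Mexiico")
  expect_identical(m$entity$standard_name, "México")
  expect_identical(m$method, "fuzzy match standard name")
  expect_identical(
    m$score, oracle_similarity(fold_name("Mexiico"), fold_name("México"))
  )
  expect_gte(m$score, 0.5)

  m <- resolve_level(world, "country", "", "Atlantis")
  expect_null(m$entity)
  expect_identical(m$method, "")
  expect_identical(m$score, 0)

  # code match wins over an identically-spelled name elsewhere in the cascade
  m <- resolve_level(world, "state_province", "usa", "AZ")
  expect_identical(m$method, "iso code")
  # alternate name, exactly
  m <- resolve_level(world, "state_province", "usa", "Ariz.")
  expect_identical(m$method, "exact match alternate name")
  expect_identical(m$score, 1)
  # class identifier stripped before exact matching
  m <- resolve_level(world, "county_parish", "usa-az", "Pima County")
  expect_identical(m$method, "exact match standard name")
})

test_that("whenever an exact variant exists it is never matched fuzzily", {
  world <- fixture_world()
  v <- scope_variants(world, "country", "")
  for (i in seq_len(nrow(v))) {
    m <- resolve_level(world, "country", "", v$text[i])
    expect_true(is_exact <- m$method %in% c(
      "iso code", "fips code", "hasc code",
      "exact match standard name", "exact match alternate name"
    ), label = paste("method for", v$text[i], "is", m$method))
    expect_identical(m$score, 1)
  }
})

test_that("full three-level combinations resolve down the hierarchy", {
  world <- fixture_world()
  r <- resolve_pdc(world, "USA", "Arizona", "Pima County")
  expect_identical(r$gid_0, "USA")
  expect_identical(r$gid_1, "USA.3_1")
  expect_identical(r$gid_2, "USA.3.11_1")
  expect_identical(r$country_iso3, "USA")
  expect_identical(r$state_province_hasc, "US.AZ")
  expect_identical(r$match_status, "full match")
  expect_identical(r$overall_score, 1)
  expect_identical(r$poldiv_submitted, "county_parish")
  expect_identical(r$poldiv_matched, "county_parish")

  r <- resolve_pdc(world, "México", "Oaxaca")
  expect_identical(r$match_status, "full match")
  expect_identical(r$overall_score, 1)
  expect_identical(r$county_parish, "")
  expect_identical(r$match_method_county_parish, "")
  expect_identical(r$poldiv_submitted, "state_province")
})

test_that("an unresolved level blocks lower levels and drags the score", {
  world <- fixture_world()
  r <- resolve_pdc(world, "USA", "Narnia", "Pima County")
  expect_identical(r$match_status, "partial match")
  expect_identical(r$state_province, "")
  expect_identical(r$county_parish, "")
  expect_identical(r$match_method_county_parish, "")
  expect_equal(r$overall_score, 1 / 3)
  expect_identical(r$poldiv_matched, "country")

  r <- resolve_pdc(world, "Atlantis", "Narnia")
  expect_identical(r$match_status, "no match")
  expect_identical(r$overall_score, 0)
  expect_identical(r$poldiv_matched, "")
})

test_that("territories recorded as states remap to their own country", {
  world <- fixture_world()
  r <- resolve_pdc(world, "USA", "Puerto Rico")
  expect_identical(r$country, "Puerto Rico")
  expect_identical(r$gid_0, "PRI")
  expect_identical(r$match_method_country, "state as country")
  expect_identical(r$match_status, "full match")
  expect_identical(r$overall_score, 1)
  expect_identical(r$poldiv_submitted, "state_province")
  expect_identical(r$poldiv_matched, "country")
})

test_that("member countries of a union remap to union + state", {
  world <- fixture_world()
  r <- resolve_pdc(world, "England")
  expect_identical(r$country, "United Kingdom")
  expect_identical(r$state_province, "England")
  expect_identical(r$match_method_country, "country as state")
  expect_identical(r$match_method_state_province, "country as state")
  expect_identical(r$match_status, "full match")
  expect_identical(r$overall_score, 1)
  expect_identical(r$poldiv_matched, "state_province")

  # a submitted state shifts down to the county position
  r <- resolve_pdc(world, "Scotland", "Kent")
  expect_identical(r$country, "United Kingdom")
  expect_identical(r$state_province, "Scotland")
  expect_identical(r$county_parish, "")
  expect_identical(r$match_status, "partial match")
  expect_equal(r$overall_score, 0.5)

  # no trigger: untouched
  r <- resolve_pdc(world, "USA", "Arizona", "Pima County")
  expect_identical(r$match_method_country, "iso code")
})

test_that("raising the threshold only removes fuzzy matches", {
  world <- fixture_world()
  v <- scope_variants(world, "country", "")
  std <- v[v$variant_class == "standard_name", ]
  withr::with_seed(23, {
    queries <- c(
      vapply(sample(std$text_norm, 15), perturb_name, ""),
      std$text[1:5] # exact inputs
    )
  })
  prev_matched <- NULL
  for (thr in c(0.3, 0.5, 0.7, 0.9)) {
    ms <- lapply(queries, function(q) {
      resolve_level(world, "country", "", q, tfuzzy = thr)
    })
    exact <- vapply(
      ms, function(m) m$method %in% c(
        "iso code", "fips code", "hasc code",
        "exact match standard name", "exact match alternate name"
      ), logical(1)
    )
    matched <- vapply(ms, function(m) !is.null(m$entity), logical(1))
    fuzzy_scores <- vapply(ms, function(m) m$score, numeric(1))[
      matched & !exact
    ]
    if (length(fuzzy_scores) > 0L) expect_true(all(fuzzy_scores >= thr))
    # exact inputs resolve identically at every threshold
    expect_true(all(matched[queries %in% std$text[1:5]]))
    expect_true(all(exact[queries %in% std$text[1:5]]))
    if (!is.null(prev_matched)) {
      # anything matched at the higher threshold was matched at the lower one
      expect_true(all(matched <= prev_matched))
    }
    prev_matched <- matched
  }
})

test_that("fuzzy choices equal the brute-force argmax over in-scope variants", {
  world <- fixture_world()
  std <- scope_variants(world, "country", "")
  std <- std[std$variant_class == "standard_name", ]
  withr::with_seed(31, {
    for (i in 1:60) {
      row <- std[sample(nrow(std), 1L), ]
      q <- perturb_name(row$text_norm, n_edits = sample(1:2, 1L))
      if (!nzchar(q)) next
      m <- resolve_level(world, "country", "", q)
      v <- scope_variants(world, "country", "")
      sims <- vapply(v$text_norm, oracle_similarity, numeric(1), a = q)
      # cascade order: standard-name candidates take precedence
      std_max <- max(sims[v$variant_class == "standard_name"])
      if (m$method == "fuzzy match standard name") {
        best <- v$entity_id[v$variant_class == "standard_name" &
          sims == std_max]
        expect_true(m$entity$entity_id %in% best)
        expect_equal(m$score, std_max)
      } else if (!is.null(m$entity)) {
        next # exact hit; covered elsewhere
      } else {
        expect_lt(std_max, 0.5)
      }
    }
  })
})

test_that("feeding matched standard names back gives exact full matches", {
  world <- fixture_world()
  first <- resolve_political_divisions(
    tibble::tibble(
      country = c("USA", "México", "Guyana"),
      state_province = c("Arizona", "Oaxaca", "Upper Takutu-Upper Essequibo"),
      county_parish = c("Pima County", "", "Yakarinta—Wowetta, Surama")
    ),
    world
  )
  second <- resolve_political_divisions(
    tibble::tibble(
      country = first$country,
      state_province = first$state_province,
      county_parish = first$county_parish
    ),
    world
  )
  expect_identical(second$gid_0, first$gid_0)
  expect_identical(second$gid_1, first$gid_1)
  expect_identical(second$gid_2, first$gid_2)
  expect_true(all(second$match_method_country == "exact match standard name"))
  expect_true(all(second$overall_score == 1))
})

test_that("matched entities always form a parent chain", {
  world <- fixture_world()
  ent <- world$entities
  counties <- ent[ent$level == "county_parish", ]
  withr::with_seed(37, {
    pick <- counties[sample(nrow(counties), min(10L, nrow(counties))), ]
  })
  states <- ent[match(pick$parent_id, ent$entity_id), ]
  countries <- ent[match(states$parent_id, ent$entity_id), ]
  res <- resolve_political_divisions(
    tibble::tibble(
      country = countries$standard_name,
      state_province = states$standard_name,
      county_parish = pick$standard_name
    ),
    world
  )
  for (i in seq_len(nrow(res))) {
    if (!nzchar(res$gid_2[i])) next
    e2 <- ent[ent$gadm_gid == res$gid_2[i], ]
    e1 <- ent[ent$entity_id == e2$parent_id, ]
    e0 <- ent[ent$entity_id == e1$parent_id, ]
    expect_identical(e1$gadm_gid, res$gid_1[i])
    expect_identical(e0$gadm_gid, res$gid_0[i])
  }
})

test_that("the batch cache is transparent and avoids recomputation", {
  world <- fixture_world()
  one <- tibble::tibble(country = rep("Costa Rica", 1000L))
  before <- poldiv:::cascade_count()
  res <- resolve_political_divisions(one, world)
  after <- poldiv:::cascade_count()
  expect_identical(after - before, 1L)
  expect_identical(nrow(res), 1000L)
  expect_identical(nrow(dplyr::distinct(res)), 1L)

  mixed <- tibble::tibble(
    user_id = as.character(1:6),
    country = c("USA", "usa", "", "Mexiico", "USA", "Guyana"),
    state_province = c("Arizona", "Arizona", "x", "", "Arizona", ""),
    county_parish = c("Pima County", "Pima County", "", "", "", "")
  )
  with_cache <- resolve_political_divisions(mixed, world, cache = TRUE)
  without <- resolve_political_divisions(mixed, world, cache = FALSE)
  expect_identical(
    as.data.frame(with_cache), as.data.frame(without)
  )
  expect_identical(nrow(with_cache), nrow(mixed))
  expect_identical(with_cache$match_status[3], "no match")
  expect_match(with_cache$note[3], "country is required")

  chunked <- resolve_political_divisions(mixed, world, chunk_size = 2L)
  expect_identical(as.data.frame(chunked), as.data.frame(with_cache))
})

test_that("a county submitted without a state is demoted with a note", {
  world <- fixture_world()
  res <- resolve_political_divisions(
    tibble::tibble(country = "USA", county_parish = "Pima County"), world
  )
  expect_identical(res$county_parish, "")
  expect_match(res$note, "county_parish ignored")
  expect_identical(res$match_status, "full match") # country level only
})

test_that("tidy and glance summarize batches", {
  world <- fixture_world()
  res <- resolve_political_divisions(
    tibble::tibble(
      country = c("USA", "Atlantis"),
      state_province = c("Arizona", "")
    ),
    world
  )
  g <- glance(res)
  expect_identical(g$n, 2L)
  expect_identical(g$n_full, 1L)
  expect_identical(g$n_no_match, 1L)
  expect_identical(g$tfuzzy, 0.5)
  td <- tidy(res)
  expect_identical(nrow(td), 3L) # 2 levels for row 1, 1 for row 2
  expect_true(all(c("level", "method", "score") %in% names(td)))
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
})
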