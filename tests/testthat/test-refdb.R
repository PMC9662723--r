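test_that("loader preserves fixture manifest counts", {
  man <- fixture_manifest()
  world <- load_ref_world(man$dir)
  expect_identical(nrow(world$entities), man$counts$entities)
  expect_identical(nrow(world$variants_raw), man$counts$name_variants)
  expect_identical(nrow(world$special_cases), man$counts$special_cases)
  expect_identical(nrow(world$lexicon), man$counts$class_identifiers)
  expect_identical(man$counts$entities, man$n_curated + man$n_extra)
})

test_that("fixture generation is deterministic for a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_fixture_world(d1, seed = 9L, n_extra = 25L)
  generate_fixture_world(d2, seed = 9L, n_extra = 25L)
  for (f in list.files(d1)) {
    expect_identical(
      unname(tools::md5sum(file.path(d1, f))),
      unname(tools::md5sum(file.path(d2, f))),
      label = f
    )
  }
  d3 <- withr::local_tempdir()
  man3 <- generate_fixture_world(d3, seed = 10L, n_extra = 25L)
  expect_identical(man3$counts$entities, man3$n_curated + 25L)
})

test_that("reloading a world twice yields identical indexes", {
  w1 <- load_ref_world(fixture_dir())
  w2 <- load_ref_world(fixture_dir())
  expect_identical(w1$entities, w2$entities)
  expect_identical(w1$variants, w2$variants)
  expect_identical(w1$special_cases, w2$special_cases)
})

test_that("generate/load/re-export round trip preserves row multisets", {
  world <- fixture_world()
  out <- withr::local_tempdir()
  write_ref_world(world, out)
  world2 <- load_ref_world(out)
  sort_tab <- function(tab) tab[do.call(order, as.list(tab)), , drop = FALSE]
  expect_equal(
    sort_tab(world$entities), sort_tab(world2$entities),
    ignore_attr = TRUE
  )
  expect_equal(
    sort_tab(world$variants_raw), sort_tab(world2$variants_raw),
    ignore_attr = TRUE
  )
  expect_equal(
    sort_tab(world$lexicon), sort_tab(world2$lexicon),
    ignore_attr = TRUE
  )
})

test_that("referential and hierarchy violations are fatal at load time", {
  world <- fixture_world()
  base <- withr::local_tempdir()

  # county attached directly to a country
  bad <- world
  bad$entities$parent_id[bad$entities$entity_id == "usa-az-pima"] <- "usa"
  d <- file.path(base, "bad-parent")
  write_ref_world(bad, d)
  expect_error(load_ref_world(d), class = "poldiv_load_error")

  # dangling parent
  bad <- world
  bad$entities$parent_id[bad$entities$entity_id == "usa-az"] <- "nowhere"
  d <- file.path(base, "dangling")
  write_ref_world(bad, d)
  expect_error(load_ref_world(d), class = "poldiv_load_error")

  # duplicate code within one scope
  bad <- world
  bad$entities$iso_alpha2[bad$entities$entity_id == "mex"] <- "US"
  d <- file.path(base, "dup-code")
  write_ref_world(bad, d)
  expect_error(load_ref_world(d), class = "poldiv_load_error")

  # missing table
  d <- file.path(base, "missing")
  write_ref_world(world, d)
  unlink(file.path(d, "meta.tsv"))
  expect_error(load_ref_world(d), "meta", class = "poldiv_load_error")
})

test_that("code lookup resolves ISO and HASC codes case-insensitively", {
  world <- fixture_world()
  usa <- lookup_code(world, "country", "", "usa")
  expect_identical(usa$standard_name, "United States")
  expect_identical(nrow(lookup_code(world, "country", "", "zz")), 0L)

  # round trip the HASC stored for Arizona through folding
  az_hasc <- world$entities$hasc_code[world$entities$entity_id == "usa-az"]
  hit <- lookup_code(world, "state_province", "usa", fold_name(az_hasc))
  expect_identical(hit$standard_name, "Arizona")
})

test_that("name lookup honours variant class and scope", {
  world <- fixture_world()
  expect_identical(
    lookup_name(world, "country", "", "united states", "standard_name")$entity_id,
    "usa"
  )
  expect_identical(
    lookup_name(world, "state_province", "usa", "ariz", "alternate_name")$entity_id,
    "usa-az"
  )
  expect_identical(
    lookup_name(world, "county_parish", "usa-az", "pima", "standard_name")$entity_id,
    "usa-az-pima"
  )
  # same string, wrong scope
  expect_identical(
    nrow(lookup_name(world, "county_parish", "mex-oax", "pima", "standard_name")),
    0L
  )
})

test_that("list_children returns sorted children and validates the parent", {
  world <- fixture_world()
  countries <- list_children(world, "", "country")
  expect_true(all(
    c("United States", "México", "Costa Rica", "Guyana") %in%
      countries$standard_name
  ))
  expect_identical(countries$standard_name, sort(countries$standard_name))
  states <- list_children(world, "usa", "state_province")
  expect_true("Arizona" %in% states$standard_name)
  expect_error(
    list_children(world, "nope", "state_province"),
    class = "poldiv_lookup_error"
  )
  expect_error(
    list_children(world, "usa", "county_parish"),
    class = "poldiv_lookup_error"
  )
})

test_that("every lookup hit lies inside the requested scope", {
  world <- fixture_world()
  states <- world$entities[world$entities$level == "state_province", ]
  for (i in seq_len(nrow(states))) {
    hit <- lookup_name(
      world, "state_province", states$parent_id[i],
      fold_name(states$standard_name[i]), "standard_name"
    )
    expect_true(states$entity_id[i] %in% hit$entity_id)
    expect_true(all(hit$parent_id == states$parent_id[i]))
  }
})
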