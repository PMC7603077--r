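test_that("the synthetic map is well-formed and round-trips through CSV", {
  map <- synthetic_phecode_map()
  expect_true(all(c("272.1", "272.11") %in% map$phecode))
  # 272.11 sits inside 272.1's hierarchy
  expect_equal(map$parent_phecode[map$phecode == "272.11"], "272.1")
  expect_equal(map$parent_phecode[map$phecode == "272.1"], "272")
  # the lipid exclusion range covers 270-279
  expect_equal(map$exclude_range_lo[map$phecode == "272.1"], 270)
  expect_equal(map$exclude_range_hi[map$phecode == "272.1"], 279)
  # every ICD code maps to exactly one phecode
  lookup <- phewasmr:::map_icd_lookup(map)
  expect_equal(anyDuplicated(lookup$icd), 0)

  path <- withr::local_tempfile(fileext = ".csv")
  make_phecode_fixture(path)
  map2 <- read_phecode_map(path)
  expect_equal(as.data.frame(map2), as.data.frame(map))
  # the packaged copy is the same map
  map3 <- read_phecode_map(phewasmr_example("phecode_map_synthetic.csv"))
  expect_equal(as.data.frame(map3), as.data.frame(map))
})

test_that("ICD mapping is dot-insensitive and propagates parents", {
  map <- synthetic_phecode_map()
  dx <- tibble::tibble(participant_id = c("p1", "p2", "p2", "p4"),
                       icd10 = c("E78.0", "e780", "E78.5", "Z99.9"))
  expect_message(sets <- map_to_phecodes(dx, map), "no phecode")
  # E78.0 -> 272.11 plus ancestors 272.1 and 272
  expect_setequal(sets$phecode[sets$participant_id == "p1"],
                  c("272.11", "272.1", "272"))
  # two codes mapping into one hierarchy: each phecode appears once
  expect_equal(anyDuplicated(sets[c("participant_id", "phecode")]), 0)
  expect_setequal(sets$phecode[sets$participant_id == "p2"],
                  c("272.11", "272.1", "272"))
  # unmapped participant contributes nothing
  expect_false("p4" %in% sets$participant_id)
  # no diagnoses -> empty set
  empty <- map_to_phecodes(dx[0, ], map)
  expect_equal(nrow(empty), 0)
})

test_that("case/control/excluded partition follows the exclusion ranges", {
  map <- synthetic_phecode_map()
  participants <- tibble::tibble(
    participant_id = c("case", "related", "healthy", "anemic"),
    sex = c("female", "male", "female", "male"))
  dx <- tibble::tibble(
    participant_id = c("case", "related", "anemic"),
    icd10 = c("E78.5",   # hyperlipidemia -> 272.1 case
              "E78.1",   # hyperglyceridemia -> 272.3, inside 270-279
              "D50"))    # iron deficiency anemia, outside the range
  sets <- map_to_phecodes(dx, map)
  cc <- build_case_control("272.1", sets, map, participants)
  expect_equal(cc$case_ids, "case")
  # a 272.3-only participant is excluded from 272.1 controls
  expect_equal(cc$excluded_ids, "related")
  expect_setequal(cc$control_ids, c("healthy", "anemic"))
  # partition: disjoint and exhaustive
  all_ids <- c(cc$case_ids, cc$control_ids, cc$excluded_ids)
  expect_setequal(all_ids, participants$participant_id)
  expect_equal(anyDuplicated(all_ids), 0)
  expect_equal(cc$n_case, 1)
  expect_equal(cc$n_control, 2)

  # participant with no phecodes is a control for every phecode
  for (ph in c("280", "250.2", "740")) {
    cci <- build_case_control(ph, sets, map, participants)
    expect_true("healthy" %in% cci$control_ids)
  }

  # zero cases is not fatal
  cc0 <- build_case_control("401", sets, map, participants)
  expect_equal(cc0$n_case, 0)
})

test_that("a child case is a parent case and never a parent control", {
  map <- synthetic_phecode_map()
  sets <- map_to_phecodes(
    tibble::tibble(participant_id = "p1", icd10 = "E78.0"), map)
  participants <- tibble::tibble(participant_id = c("p1", "p2"),
                                 sex = "female")
  cc <- build_case_control("272.1", sets, map, participants)
  expect_equal(cc$case_ids, "p1")  # 272.11 diagnosis makes a 272.1 case
  expect_false("p1" %in% cc$control_ids)
  expect_false("p1" %in% cc$excluded_ids)
})

test_that("sex-specific phecodes restrict the analyzable cohort", {
  map <- synthetic_phecode_map()
  participants <- tibble::tibble(
    participant_id = c("f1", "f2", "m1"),
    sex = c("female", "female", "male"))
  sets <- map_to_phecodes(
    tibble::tibble(participant_id = "f1", icd10 = "D25"), map)
  cc <- build_case_control("218", sets, map, participants)  # female-only
  expect_equal(cc$case_ids, "f1")
  expect_equal(cc$control_ids, "f2")
  expect_false("m1" %in% c(cc$case_ids, cc$control_ids, cc$excluded_ids))
})

test_that("partition invariant holds across simulated cohorts", {
  iron <- iron_set()
  cfg <- sim_config(iron, n = 2000, seed = 31)
  co <- simulate_cohort(cfg)
  sets <- map_to_phecodes(co$diagnoses, co$map)
  for (ph in c("272.1", "280", "454.1", "218")) {
    cc <- build_case_control(ph, sets, co$map, co$participants)
    ids <- c(cc$case_ids, cc$control_ids, cc$excluded_ids)
    expect_equal(anyDuplicated(ids), 0)
    row <- co$map[co$map$phecode == ph, ]
    expected_n <- if (row$sex == "both") nrow(co$participants) else
      sum(co$participants$sex == row$sex)
    expect_length(ids, expected_n)
  }
})
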