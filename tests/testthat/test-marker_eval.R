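# Verdicts, sex calls and panel recommendation.

mk_pair <- function(marker = "MX", z = 923L, second = 510L,
                    location = "W", partial = FALSE, species = "S1") {
  data.frame(marker_id = marker, species_id = species, z_seq = "chrZ",
             z_length = z, second_seq = "chrW",
             second_length = if (is.na(second)) NA_integer_ else second,
             second_location = location, partial = partial,
             delta_L = if (location == "absent" || partial) NA_integer_
                       else abs(z - second),
             z_longer = if (location == "absent" || partial) NA
                        else z > second,
             identity = 0.95, query_cover = if (partial) 0.57 else 1,
             stringsAsFactors = FALSE)
}

test_that("verdict mapping is total and matches the decision rules", {
  expect_equal(evaluate_marker(mk_pair())$verdict, "informative")
  expect_equal(evaluate_marker(mk_pair())$gel_pct_required, 1)
  expect_equal(evaluate_marker(mk_pair(second = NA,
                                       location = "absent"))$verdict,
               "z_only")
  expect_equal(evaluate_marker(mk_pair(second = 526,
                                       partial = TRUE))$verdict,
               "partial_copy_only")
  expect_equal(evaluate_marker(mk_pair(z = 364, second = 364,
                                       location = "scaffold"))$verdict,
               "unresolvable_polymorphism")
  nf <- evaluate_marker(data.frame(marker_id = "MX", species_id = "S1",
                                   z_length = NA_integer_))
  expect_equal(nf$verdict, "not_found")
  # an 11 bp difference near 370 bp: informative, but only on a 3% gel
  v <- evaluate_marker(mk_pair(z = 367, second = 378, location = "scaffold"))
  expect_equal(v$verdict, "informative")
  expect_equal(v$gel_pct_required, 3)
})

test_that("nonspecific bands in the diagnostic window confound a marker", {
  v_clear <- evaluate_marker(mk_pair(), nonspecific = 2000)
  expect_equal(v_clear$verdict, "informative")
  expect_match(v_clear$notes, "clear")
  v_conf <- evaluate_marker(mk_pair(), nonspecific = 915)
  expect_equal(v_conf$verdict, "confounded")
})

test_that("sex calls follow the two-band female / one-band male rule", {
  v <- evaluate_marker(mk_pair())  # informative at 1%
  expect_equal(sex_call(c(923, 510), v)$call, "female")
  expect_equal(sex_call(923, v)$call, "male")
  expect_equal(sex_call(numeric(), v)$call, "indeterminate")
  # one band under a non-informative verdict is never called male
  vz <- evaluate_marker(mk_pair(second = NA, location = "absent"))
  expect_equal(sex_call(923, vz)$call, "indeterminate")
  # two bands closer than the gel can separate do not make a female
  v2 <- evaluate_marker(mk_pair(z = 504, second = 461,
                                location = "scaffold"))
  expect_equal(sex_call(c(504, 503), v2)$call, "male")
})

test_that("panel ranking is deterministic and permutation-invariant", {
  verdicts <- rbind(
    evaluate_marker(mk_pair("M7", 923, 510, species = "S2")),
    evaluate_marker(mk_pair("M4", 504, 461, location = "scaffold",
                            species = "S2")),
    evaluate_marker(mk_pair("M1", 367, 378, location = "scaffold",
                            species = "S2")),
    evaluate_marker(mk_pair("M7", 923, NA, location = "absent",
                            species = "S1")),
    evaluate_marker(mk_pair("M3", 2997, 623, location = "scaffold",
                            species = "S1")))
  p <- recommend_panel(verdicts)
  expect_equal(p$marker_id[p$species_id == "S2" & p$rank == 1], "M7")
  expect_equal(p$marker_id[p$species_id == "S1" & p$rank == 1], "M3")
  p2 <- recommend_panel(verdicts[sample(nrow(verdicts)), ])
  expect_identical(p, p2)
})

test_that("a species with no informative marker gets an explanatory row", {
  verdicts <- rbind(
    evaluate_marker(mk_pair("M1", second = NA, location = "absent")),
    evaluate_marker(mk_pair("M2", z = 364, second = 364,
                            location = "scaffold")))
  p <- recommend_panel(verdicts)
  expect_true(all(is.na(p$marker_id)))
  expect_match(p$note, "no informative")
  rep <- species_report(verdicts)
  expect_true(any(grepl("Recommended marker: none", rep)))
})

test_that("sex calls on simulated gels are correct or indeterminate, never wrong", {
  # planted truth: female = both copies, male = Z only
  for (seed in c(21L, 22L, 23L)) {
    cfg <- random_sim_config(seed, delta_range = c(1L, 600L))
    sim <- simulate_zw(cfg)
    run <- run_marker_pipeline(sim, sim$primers)
    v <- run$verdicts[run$verdicts$marker_id == "MZ1", ]
    tr <- sim$truth$markers
    female_bands <- c(tr$z_length, tr$second_span)
    male_bands <- tr$z_length
    if (v$verdict == "informative") {
      expect_true(sex_call(male_bands, v)$call %in%
                    c("male", "indeterminate"))
      expect_true(sex_call(female_bands, v)$call %in%
                    c("female", "indeterminate"))
    } else {
      expect_equal(sex_call(female_bands, v)$call, "indeterminate")
    }
  }
})
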