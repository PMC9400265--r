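test_that("citation frequency reproduces the survey demographics", {
  # 358 of 756 informants aged 36-50; 401 of 756 in the Sudanian zone
  expect_equal(round_display(citation_frequency(358, 756), 2), 47.35)
  expect_equal(round_display(citation_frequency(401, 756), 2), 53.04)
  expect_equal(citation_frequency(0, 10), 0)
  expect_error(citation_frequency(1, 0), "undefined denominator")
  expect_error(citation_frequency(5, 4), "0 <= Np <= Nt")
})

test_that("per-informant use value counts distinct use-reports", {
  d <- tiny_survey()
  # i1 cited 2 reports for sp_A (jaundice remedy on rootstock, sauce on leaf)
  expect_equal(informant_use_value(d, "i1", "sp_A"), 2)
  expect_equal(informant_use_value(d, "i4", "sp_B"), 0)
  expect_error(informant_use_value(d, "ghost", "sp_A"), "unknown informant")
  # the same specific use on two organs is two reports
  ur <- tibble::tibble(
    informant_id = "i1", species = "sp_A",
    organ = c("rootstock", "leaf"), category = "medicinal",
    specific_use = "jaundice remedy", affection_category = NA_character_
  )
  d2 <- interview_set(d$informants, ur, d$responses, d$species_list)
  expect_equal(informant_use_value(d2, "i1", "sp_A"), 2)
  # brute-force recount of distinct (organ, category, use) triples
  n_oracle <- nrow(unique(ur[, c("organ", "category", "specific_use")]))
  expect_equal(informant_use_value(d2, "i1", "sp_A"), n_oracle)
})

test_that("species use value is the mean over informants who know it", {
  d <- tiny_survey()
  # sp_A: i1 cites 2, i2 cites 1, i3 cites 1; i4 excluded (does not know)
  uv <- species_use_value(d, "sp_A")
  expect_equal(uv$ns, 3)
  expect_equal(uv$uvs, mean(c(2, 1, 1)))
  expect_equal(uv$sd, sd(c(2, 1, 1)))
  # population sd on request
  uvp <- species_use_value(d, "sp_A", sd_type = "population")
  expect_equal(uvp$sd, sqrt(mean((c(2, 1, 1) - 4 / 3)^2)))
  # zero-citing informants drag the mean down but stay in Ns
  uvB <- species_use_value(d, "sp_B")
  expect_equal(uvB$ns, 4)
  expect_equal(uvB$uvs, mean(c(1, 0, 1, 0)))
  # group scoping
  uvZ <- species_use_value(d, "sp_A", group = "Zerma")
  expect_equal(uvZ$ns, 1)
  expect_equal(uvZ$uvs, 1)
  expect_equal(uvZ$sd, 0)
  expect_error(species_use_value(subset_interviews(d, ethnic_group = "Zerma"),
                                 "sp_A", group = "Mokolé"),
               "lookup error|undefined")
})

test_that("use values match an independent recount from the written CSV", {
  sim <- generate_survey(synthetic_config(n_groups = 3,
                                          informants_per_group = 30,
                                          seed = 11))
  d <- sim$interviews
  sp <- d$species_list
  path <- withr::local_tempfile(fileext = ".csv")
  write_interviews(d, path)
  raw <- utils::read.csv(path, encoding = "UTF-8")
  for (g in unique(d$informants$ethnic_group)) {
    ids <- raw$informant_id[raw$ethnic_group == g & !duplicated(raw$informant_id)]
    per_inf <- vapply(ids, function(i) {
      sum(raw$informant_id == i & !is.na(raw$specific_use))
    }, numeric(1))
    expect_equal(species_use_value(d, sp, group = g)$uvs, mean(per_inf))
    # per-category totals equal a naive group-by count on raw rows
    uvc <- category_use_value(d, sp, group = g)
    cited <- raw[raw$ethnic_group == g & !is.na(raw$specific_use), ]
    for (cat in names(uvc)) {
      expect_equal(unname(uvc[cat]), sum(cited$category == cat))
    }
  }
})

test_that("category use values cover the vocabulary with zero fills", {
  d <- tiny_survey()
  uvc <- category_use_value(d, "sp_A", group = "Mokolé")
  expect_setequal(names(uvc), default_vocabulary()$categories)
  expect_equal(unname(uvc["medicinal"]), 1)
  expect_equal(unname(uvc["food"]), 1)
  expect_equal(unname(uvc["dye"]), 1)
  expect_equal(unname(uvc["fuel"]), 0)
  expect_equal(category_use_value(d, "sp_A", group = "Mokolé", scale = 2),
               uvc * 2)
})

test_that("organ index is a tally normalization summing to one", {
  d <- tiny_survey()
  ivo <- organ_index(d, "sp_A")
  expect_equal(sum(ivo), 1)
  expect_equal(unname(ivo["rootstock"]), 3 / 4)
  expect_equal(unname(ivo["leaf"]), 1 / 4)
  d_one <- subset_interviews(d, species = "sp_B")
  ivoB <- organ_index(d_one, "sp_B")
  expect_equal(sum(ivoB), 1)
  empty <- interview_set(d$informants, responses = d$responses,
                         species_list = d$species_list)
  expect_error(organ_index(empty, "sp_A"), "undefined organ index")
})

test_that("commercial value index and flagging follow the 75% rule", {
  expect_equal(commercial_value_index(3, 4), 75)
  expect_equal(commercial_value_index(0, 5), 0)
  expect_equal(commercial_value_index(5, 5), 100)
  expect_error(commercial_value_index(1, 0), "undefined denominator")
  # the boundary sits at >= by default, > under strict
  expect_true(flag_commercially_important(87.80))
  expect_false(flag_commercially_important(66.67))
  expect_true(flag_commercially_important(75))
  expect_false(flag_commercially_important(75, strict = TRUE))
  d <- tiny_survey()
  # sp_A sellers: i1, i3 of 3 interviewed (i4 excluded)
  expect_equal(commercial_value(d, "sp_A"), 100 * 2 / 3)
})

test_that("index normalization and bounds hold on random synthetic surveys", {
  for (seed in 1:100) {
    cfg <- synthetic_config(
      n_groups = sample(2:5, 1), informants_per_group = sample(3:10, 1),
      coupling_beta = stats::runif(1, 0, 1), seller_prob = stats::runif(1),
      seed = seed
    )
    sim <- generate_survey(cfg)
    d <- sim$interviews
    sp <- d$species_list
    if (nrow(d$use_reports) == 0) next
    ivo <- organ_index(d, sp)
    expect_equal(sum(ivo), 1, tolerance = 1e-12)
    icv <- commercial_value(d, sp)
    expect_gte(icv, 0)
    expect_lte(icv, 100)
    fc <- citation_frequency(
      sum(d$responses$perceived_dynamic %in% "decrease"),
      nrow(d$responses)
    )
    expect_gte(fc, 0)
    expect_lte(fc, 100)
  }
})

test_that("adding a use-report never decreases UVis, UVs or UVc", {
  d <- tiny_survey()
  before_uv <- species_use_value(d, "sp_A")$uvs
  before_uvis <- informant_use_value(d, "i2", "sp_A")
  before_uvc <- category_use_value(d, "sp_A")
  d$use_reports <- dplyr::bind_rows(
    d$use_reports,
    tibble::tibble(informant_id = "i2", species = "sp_A", organ = "fruit",
                   category = "food", specific_use = "snack",
                   affection_category = NA_character_)
  )
  validate_interviews(d)
  expect_gte(informant_use_value(d, "i2", "sp_A"), before_uvis)
  expect_gte(species_use_value(d, "sp_A")$uvs, before_uv)
  after_uvc <- category_use_value(d, "sp_A")
  expect_true(all(after_uvc >= before_uvc))
})

test_that("indices are invariant to duplicating every informant", {
  d <- tiny_survey()
  clone <- function(df) {
    df2 <- df
    df2$informant_id <- paste0(df2$informant_id, "_dup")
    df2
  }
  d2 <- interview_set(
    dplyr::bind_rows(d$informants, clone(d$informants)),
    dplyr::bind_rows(d$use_reports, clone(d$use_reports)),
    dplyr::bind_rows(d$responses, clone(d$responses)),
    d$species_list, d$vocabulary
  )
  expect_equal(species_use_value(d2, "sp_A")$uvs,
               species_use_value(d, "sp_A")$uvs)
  expect_equal(organ_index(d2, "sp_A"), organ_index(d, "sp_A"))
  expect_equal(commercial_value(d2, "sp_A"), commercial_value(d, "sp_A"))
})

test_that("lexicon normalizer rescales UV without reordering groups", {
  sim <- generate_survey(synthetic_config(n_groups = 4,
                                          informants_per_group = 12,
                                          seed = 3))
  d <- sim$interviews
  sp <- d$species_list
  lex <- length(unique(d$use_reports$specific_use))
  raw <- vapply(sort(unique(d$informants$ethnic_group)), function(g) {
    species_use_value(d, sp, group = g)$uvs
  }, numeric(1))
  norm <- vapply(sort(unique(d$informants$ethnic_group)), function(g) {
    species_use_value(d, sp, group = g, uv_normalizer = "lexicon")$uvs
  }, numeric(1))
  expect_equal(norm, raw / lex)
  expect_equal(order(norm), order(raw))
})
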