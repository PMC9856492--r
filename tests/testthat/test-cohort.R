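rel <- function(degree, diagnosis, age, confirmed = TRUE) {
  data.frame(degree = degree, diagnosis = diagnosis, age_at_dx = age,
             confirmed = confirmed)
}
pat <- function(age, histology = "diffuse", lobular = FALSE) {
  list(age_at_dx = age, histology = histology,
       personal_lobular_breast = lobular)
}

test_that("each qualifying condition is recognized on canonical cases", {
  ## early-onset diffuse GC, no family history -> condition 3 only
  r <- classifyHdgc(pat(35))
  expect_equal(r$conditions_met, 3L)
  expect_true(r$eligible)
  ## three confirmed diffuse relatives at any age -> condition 2
  fam <- rbind(rel(1, "diffuse_GC", 60), rel(1, "diffuse_GC", 62),
               rel(2, "diffuse_GC", 70))
  r <- classifyHdgc(pat(45), fam)
  expect_equal(r$conditions_met, 2L)
  ## two GC relatives incl. a confirmed diffuse case before 50 -> condition 1
  fam <- rbind(rel(1, "GC", 55, confirmed = FALSE), rel(2, "diffuse_GC", 45))
  r <- classifyHdgc(pat(50), fam)
  expect_equal(r$conditions_met, 1L)
  ## lobular breast cancer plus own diffuse GC before 50 -> condition 4
  fam <- rel(1, "lobular_breast", 60)
  r <- classifyHdgc(pat(45), fam)
  expect_equal(r$conditions_met, 4L)
  ## intestinal histology, no family history -> ineligible
  r <- classifyHdgc(pat(45, histology = "other"))
  expect_false(r$eligible)
  expect_length(r$conditions_met, 0)
  expect_error(classifyHdgc(pat(45, histology = "mixed")), "histology")
})

test_that("condition-1 readings differ exactly as configured", {
  ## two GC relatives but no confirmed diffuse case before 50
  fam <- rbind(rel(1, "GC", 55, confirmed = FALSE),
               rel(1, "GC", 60, confirmed = FALSE))
  strict <- classifyHdgc(pat(50), fam, condition1 = "strict")
  lenient <- classifyHdgc(pat(50), fam, condition1 = "lenient")
  expect_false(1L %in% strict$conditions_met)
  expect_true(1L %in% lenient$conditions_met)
  ## a single confirmed diffuse relative before 50
  fam <- rel(1, "diffuse_GC", 45)
  strict <- classifyHdgc(pat(50), fam, condition1 = "strict")
  lenient <- classifyHdgc(pat(50), fam, condition1 = "lenient")
  expect_false(1L %in% strict$conditions_met)
  expect_true(1L %in% lenient$conditions_met)
})

test_that("conditions are monotone in qualifying relatives", {
  set.seed(77)
  diagnoses <- c("GC", "diffuse_GC", "lobular_breast")
  for (rep in 1:30) {
    n <- sample(0:4, 1)
    fam <- if (n) data.frame(degree = sample(1:2, n, TRUE),
                             diagnosis = sample(diagnoses, n, TRUE),
                             age_at_dx = sample(30:75, n, TRUE),
                             confirmed = sample(c(TRUE, FALSE), n, TRUE))
    else NULL
    p <- pat(sample(25:60, 1))
    before <- classifyHdgc(p, fam)$conditions_met
    extra <- rbind(fam, rel(1, "diffuse_GC", 44))
    after <- classifyHdgc(p, extra)$conditions_met
    ## adding a qualifying relative may only remove condition 3
    expect_true(all(setdiff(before, 3L) %in% after))
  }
})

test_that("a condition-3 patient has no diffuse family history by construction", {
  fam <- rel(1, "diffuse_GC", 60)
  r <- classifyHdgc(pat(30), fam)
  expect_false(3L %in% r$conditions_met)
  r <- classifyHdgc(pat(30), rel(1, "GC", 60, confirmed = FALSE))
  expect_true(3L %in% r$conditions_met)  # non-diffuse GC history is allowed
})

test_that("cohort composition reports exact one-decimal percentages", {
  clinical <- data.frame(
    patient_id = sprintf("P%02d", 1:10),
    age_at_dx = c(rep(30, 9), 45),
    histology = "diffuse",
    sex = c(rep("female", 6), rep("male", 4)),
    personal_lobular_breast = FALSE,
    t_category = "T3", n_category = "N2", m_category = "M0",
    stage = "III", ebv_status = "negative")
  elig <- classifyHdgcCohort(clinical)
  comp <- cohortComposition(clinical, elig)
  gp <- function(cat, lev) comp$percent[comp$category == cat &
                                          comp$level == lev]
  expect_equal(gp("sex", "female"), 60.0)
  expect_equal(gp("age", "<40"), 90.0)
  expect_equal(gp("condition", "3"), 90.0)
  expect_equal(gp("condition", "4"), 0.0)
  expect_error(cohortComposition(clinical[0, ], elig), "at least one")
})

test_that("a planted condition mix is recovered exactly on synthetic cohorts", {
  b <- cachedBundle("small", smallConfig())
  clin <- read.delim(file.path(bundleDir(b), "clinical.tsv"))
  fam <- read.delim(file.path(bundleDir(b), "family.tsv"))
  elig <- classifyHdgcCohort(clin, fam)
  for (k in 1:4) {
    planted <- clin$planted_condition == as.character(k)
    expect_equal(sum(elig$first_condition == k, na.rm = TRUE), sum(planted),
                 info = paste("condition", k))
  }
  expect_equal(elig$eligible, clin$planted_condition != "none")
})
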