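test_that("conflict measures mass on incompatible focal pairs", {
  fr <- c("A", "B")
  vac <- vacuous_mass(fr)
  expect_equal(conflict(vac, vac), 0)
  mA <- mass_function(fr, list("A"), 1)
  mB <- mass_function(fr, list("B"), 1)
  expect_equal(conflict(mA, mB), 1)
  m1 <- mass_function(fr, list("A", "B"), c(0.6, 0.4))
  m2 <- mass_function(fr, list("A", "B"), c(0.7, 0.3))
  expect_equal(conflict(m1, m2), 0.46)           # 0.6*0.3 + 0.4*0.7
  expect_equal(conflict(m1, m2), conflict(m2, m1))
  m3 <- mass_function(c("A", "C"), list("A"), 1)
  expect_error(conflict(m1, m3), "frames")
})

test_that("Dempster combination renormalizes joint masses by 1 - K", {
  fr <- c("A", "B")
  m1 <- mass_function(fr, list("A", "B"), c(0.6, 0.4))
  m2 <- mass_function(fr, list("A", "B"), c(0.7, 0.3))
  m12 <- combine_bpa(m1, m2)
  expect_equal(mass_of(m12, "A"), 0.42 / 0.54, tolerance = 1e-12)
  expect_equal(mass_of(m12, "B"), 0.12 / 0.54, tolerance = 1e-12)
  expect_equal(sum(m12$mass), 1, tolerance = 1e-12)

  # vacuous evidence is the identity element
  vac <- vacuous_mass(fr)
  mv <- combine_bpa(m1, vac)
  expect_equal(mass_of(mv, "A"), 0.6)
  expect_equal(mass_of(mv, "B"), 0.4)

  # total conflict is undefined
  expect_error(combine_bpa(mass_function(fr, list("A"), 1),
                           mass_function(fr, list("B"), 1)),
               "total conflict")
})

test_that("combine_many folds pairwise combination and is order-invariant", {
  fr <- c("A", "B", "C")
  set.seed(3)
  ms <- replicate(4, random_mass(fr, 5), simplify = FALSE)
  expect_identical(combine_many(ms[1]), ms[[1]])
  ref <- combine_many(ms)
  for (rep in 1:5) {
    perm <- combine_many(ms[sample(4)])
    for (i in seq_along(ref$focal))
      expect_equal(mass_of(perm, ref$focal[[i]]), ref$mass[i], tolerance = 1e-9)
  }
  vac <- vacuous_mass(fr)
  v3 <- combine_many(list(vac, vac, vac))
  expect_equal(mass_of(v3, fr), 1)
  expect_error(combine_many(list()), "at least one")
})

test_that("combination matches the naive enumeration oracle on random inputs", {
  set.seed(17)
  for (i in 1:40) {
    fr <- LETTERS[seq_len(sample(2:4, 1))]
    m1 <- random_mass(fr); m2 <- random_mass(fr)
    expect_equal(conflict(m1, m2), oracle_conflict(m1, m2), tolerance = 1e-12)
    if (oracle_conflict(m1, m2) < 1 - 1e-9) {
      got <- combine_bpa(m1, m2)
      ora <- oracle_combine(m1, m2)
      for (s in seq_along(ora$sets))
        expect_equal(mass_of(got, ora$sets[[s]]), ora$mass[s], tolerance = 1e-9)
      expect_equal(sum(got$mass), 1, tolerance = 1e-9)
    }
  }
})

test_that("mass functions survive a JSON round trip", {
  m <- mass_function(c("A", "B", "C"), list(c("A", "B"), "C", c("A", "B", "C")),
                     c(0.5, 0.3, 0.2))
  back <- mass_from_json(mass_to_json(m))
  expect_equal(back$frame, m$frame)
  for (i in seq_along(m$focal))
    expect_equal(mass_of(back, m$focal[[i]]), m$mass[i])
})

test_that("dataset fusion concatenates sources and reports counts", {
  spec <- synthetic_spec(sources = c(big = 60L, small = 25L), seed = 2)
  srcs <- generate_sources(spec)
  fused <- fuse_datasets(srcs)
  expect_equal(fused$report$n_out, 85L)
  expect_equal(unname(fused$report$n_in_per_source), c(60L, 25L))
  expect_equal(fused$report$duplicates_removed, 0L)
  # records preserved bit-exactly, source tags intact
  expect_identical(fused$dataset$values[1:60, ], srcs$big$values)
  expect_identical(fused$dataset$values[61:85, ], srcs$small$values)
  expect_equal(as.vector(table(fused$dataset$sources)[c("big", "small")]), c(60L, 25L))

  # single source is the identity
  solo <- fuse_datasets(srcs["big"])
  expect_identical(solo$dataset$values, srcs$big$values)

  # exact duplicates collapse under dedup
  twice <- fuse_datasets(list(srcs$small, srcs$small), dedup = TRUE)
  expect_equal(twice$report$n_out, 25L)
  expect_equal(twice$report$duplicates_removed, 25L)
  expect_equal(twice$report$n_out + twice$report$duplicates_removed,
               sum(twice$report$n_in_per_source))

  # schema mismatch names the offending source and column
  bad <- srcs$small
  colnames(bad$values)[3] <- "SomethingElse"
  expect_error(fuse_datasets(list(srcs$big, bad)), "source 2.*BloodPressure")
})
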