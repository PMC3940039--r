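# NOE build-up factor, jump/centroid rates, table prediction, scaling

test_that("build-up rate factor has the right limits, zero crossing, and slow-tumbling sign", {
  # extreme narrowing: factor -> 2 tau_c
  tc <- 1e-12
  expect_equal(buildup_rate_factor(tc, 2 * pi * 600e6), 2 * tc, tolerance = 1e-4)
  # analytic zero crossing of 6 J(2w) = J(0) at (w tau_c) = sqrt(5)/2
  w <- 2 * pi * 600e6
  tc0 <- sqrt(5) / 2 / w
  expect_lt(abs(buildup_rate_factor(tc0, w)), 1e-12)
  # a 5.8 ns tumbler at 600 MHz is in the negative-NOE regime
  expect_lt(buildup_rate_factor(5.8e-9, w), 0)
  expect_error(buildup_rate_factor(0, w), "positive")
})

test_that("jump rate collapses to 1/d^6 in the far field and cancels by construction", {
  # tiny methyl radius, probe on the 3-fold axis at distance d
  d <- 10
  eps <- 1e-3
  protons <- rbind(c(eps, 0, 0), c(-eps / 2, eps * sqrt(3) / 2, 0),
                   c(-eps / 2, -eps * sqrt(3) / 2, 0))
  g <- methyl_probe_geometry(list(protons = protons), c(0, 0, d))
  expect_equal(jump_effective_rate(g) * d^6, 1, tolerance = 1e-4)

  # equidistant probe with all off-diagonal angles at 90 degrees:
  # (1/18) [3 * 2/r^6 + 6 * (-1)/r^6] = 0
  r <- 3
  protons90 <- r * diag(3)
  g90 <- methyl_probe_geometry(list(protons = protons90), c(0, 0, 0))
  expect_equal(jump_effective_rate(g90), 0, tolerance = 1e-15)
})

test_that("jump rate equals the spherical-harmonic contraction oracle on random geometries", {
  set.seed(101)
  worst <- 0
  for (i in 1:1000) {
    ctr <- rnorm(3, sd = 3)
    protons <- matrix(rnorm(9, sd = 0.9), 3, 3) + matrix(ctr, 3, 3, byrow = TRUE)
    probe <- ctr + runif(1, 2.5, 9) * {
      v <- rnorm(3); v / sqrt(sum(v^2))
    }
    g <- methyl_probe_geometry(list(protons = protons), probe)
    a <- jump_effective_rate(g)
    b <- sh_rate_oracle(protons, probe)
    worst <- max(worst, abs(a - b) / max(abs(b), 1e-12))
  }
  expect_lt(worst, 1e-8)
})

test_that("centroid rates follow r^-6 and reproduce a printed gating distance", {
  m <- list(carbon = c(0, 0, 0),
            protons = rbind(c(0.9, 0.4, 0.3), c(-0.9, 0.4, 0.3), c(0, -1, 0.3)))
  expect_equal(centroid_rate(m, c(1, 0, 0), "carbon"), 1)
  # the strongest wild-type methyl sits 4.14 A from the indole proton
  expect_equal(centroid_rate(m, c(4.14, 0, 0), "carbon"), 4.14^-6)
  mp <- colMeans(m$protons)
  expect_equal(centroid_rate(m, c(5, 5, 5), "mean-proton"),
               sum((c(5, 5, 5) - mp)^2)^-3)
  expect_error(centroid_rate(m, c(0, 0, 0), "carbon"), "domain error")
})

test_that("the three interaction models converge in the far field", {
  vf <- valine_fragment()
  m <- build_methyl_protons(vf, selection = "A:30:CG1")[[1]]
  # jump vs mean-proton: the first-order term cancels (the protons are
  # symmetric about their centroid), so agreement is second order in
  # radius/d and already < 1% at 50 A
  probe <- m$carbon + 50 * c(0.36, 0.48, 0.8)
  r_jump <- jump_effective_rate(methyl_probe_geometry(m, probe))
  expect_lt(abs(r_jump / centroid_rate(m, probe, "mean-proton") - 1), 0.01)
  # the carbon centroid sits ~0.36 A off the proton plane, a first-order
  # offset: ~6*(0.36/d) relative, so < 1% only at larger distances
  expect_lt(abs(r_jump / centroid_rate(m, probe, "carbon") - 1),
            6 * 0.37 / 50 + 0.01)
  probe_far <- m$carbon + 500 * c(0.36, 0.48, 0.8)
  r_jump_far <- jump_effective_rate(methyl_probe_geometry(m, probe_far))
  expect_lt(abs(r_jump_far / centroid_rate(m, probe_far, "carbon") - 1), 0.01)
  expect_lt(abs(r_jump_far / centroid_rate(m, probe_far, "mean-proton") - 1), 1e-4)
})

test_that("predicted tables are gated, normalized, and merge degenerate methyls", {
  sc <- make_scene(seed = 5)
  tab <- predict_noe_table(sc$structure_a, sc$probe_sel, cutoff = 7)
  expect_s3_class(tab, "noe_table")
  expect_true(all(tab$gating_distance_A <= 7))
  expect_equal(max(tab$normalized_volume), 1.0)
  expect_equal(sum(tab$normalized_volume == 1), 1)
  expect_true(all(tab$normalized_volume >= 0 & tab$normalized_volume <= 1))

  # merging two entries sums their raw rates before normalization
  if (nrow(tab) >= 2) {
    r1 <- tab$resno[1]; a1 <- tab$methyl_atom[1]
    r2 <- tab$resno[2]; a2 <- tab$methyl_atom[2]
    mm <- data.frame(from_resno = r1, from_atom = a1,
                     to_resno = r2, to_atom = a2)
    tab2 <- predict_noe_table(sc$structure_a, sc$probe_sel, cutoff = 7, merge = mm)
    expect_equal(nrow(tab2), nrow(tab) - 1)
    i2 <- which(tab2$resno == r2 & tab2$methyl_atom == a2)
    expect_equal(tab2$raw_rate[i2], tab$raw_rate[1] + tab$raw_rate[2],
                 tolerance = 1e-12)
    expect_match(tab2$merged_from[i2], paste0(r1, ":", a1), fixed = TRUE)
  }

  # exclusion drops an in-cutoff methyl
  key1 <- sprintf("%s:%d:%s", tab$chain[1], tab$resno[1], tab$methyl_atom[1])
  tab3 <- predict_noe_table(sc$structure_a, sc$probe_sel, cutoff = 7,
                            exclude = key1)
  expect_equal(nrow(tab3), nrow(tab) - 1)

  # a single methyl normalizes to exactly 1 under every model
  one <- sprintf("A:%d:CG1", tab$resno[1])
  for (mo in c("jump", "carbon", "mean-proton")) {
    t1 <- predict_noe_table(sc$structure_a, sc$probe_sel, methyl_sel = one,
                            model = mo)
    expect_equal(t1$normalized_volume, 1.0)
  }

  # no methyl in range: warning and empty table, not an error
  expect_warning(
    t0 <- predict_noe_table(sc$structure_a, sc$probe_sel, cutoff = 1.9),
    "no methyl")
  expect_equal(nrow(t0), 0)
})

test_that("cross-structure scale is 1 for identical structures and matches printed distances", {
  sc <- make_scene(seed = 5)
  ta <- predict_noe_table(sc$structure_a, sc$probe_sel)
  expect_equal(cross_structure_scale(ta, ta), 1.0)
  tb <- predict_noe_table(sc$structure_b, sc$probe_sel, model = "carbon")
  expect_error(cross_structure_scale(ta, tb), "configuration error")

  # carbon-centroid scale from the packaged gating distances:
  # strongest methyls at 4.14 A (wild-type) and 3.32 A (flipped)
  fit <- fkbp12_carbon_mixture_fit()
  expect_equal(fit$scale, (3.32 / 4.14)^6, tolerance = 1e-12)
  expect_equal(fit$scale, 0.266, tolerance = 1e-3)
})

test_that("table export round-trips through TSV and JSON", {
  sc <- make_scene(seed = 5)
  tab <- predict_noe_table(sc$structure_a, sc$probe_sel)
  ft <- tempfile(fileext = ".tsv")
  write_noe_table(tab, ft)
  back <- utils::read.table(ft, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$normalized_volume, tab$normalized_volume, tolerance = 1e-12)
  fj <- tempfile(fileext = ".json")
  write_noe_table_json(tab, fj)
  js <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(js$max_raw_rate, attr(tab, "max_raw"), tolerance = 1e-12)
  expect_equal(js$entries$raw_rate, tab$raw_rate, tolerance = 1e-12)
})
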