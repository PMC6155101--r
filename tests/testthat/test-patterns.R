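test_that("sign classification is total with 0 counted positive", {
  expect_equal(sign_of(c(15, 0, -0.001, 180, -179.9)),
               c("+", "+", "-", "+", "-"))
  expect_error(sign_of(-180), class = "bj_domain")
  expect_error(sign_of(181), class = "bj_domain")
})

test_that("dyad counts slide a width-2 window over one sign string", {
  d <- dyad_counts(c("+", "+", "+"))
  expect_equal(d$n[d$pattern == "(+,+)"], 2)
  expect_equal(sum(d$n), 2)

  d2 <- dyad_counts("+-+")
  expect_equal(d2$n[d2$pattern == "(+,-)"], 1)
  expect_equal(d2$n[d2$pattern == "(-,+)"], 1)
  expect_equal(sum(d2$n), 2)

  expect_equal(sum(dyad_counts(character(0))$n), 0)
  expect_equal(sum(dyad_counts("+")$n), 0)
  expect_equal(nrow(d), 4)
  expect_equal(d$pattern, c("(+,+)", "(+,-)", "(-,+)", "(-,-)"))
})

test_that("triad counts cover the eight ordered sign triples", {
  t1 <- triad_counts("++++")
  expect_equal(t1$n[t1$pattern == "(+,+,+)"], 2)
  expect_equal(sum(t1$n), 2)
  t2 <- triad_counts("+-+-")
  expect_equal(t2$n[t2$pattern == "(+,-,+)"], 1)
  expect_equal(t2$n[t2$pattern == "(-,+,-)"], 1)
  expect_equal(sum(triad_counts("+-")$n), 0)
  expect_equal(nrow(t1), 8)
})

test_that("quadrants partition the angle domain with pinned boundaries", {
  expect_equal(quadrant_of(c(120, 0, -90, 45, 90, 180, -0.5, -179)),
               c("+B", "+A", "-A", "+A", "+B", "+B", "-A", "-B"))
  set.seed(5)
  a <- runif(500, -179.999, 180)
  q <- quadrant_of(a)
  expect_true(all(q %in% c("+A", "+B", "-A", "-B")))
  # every angle in exactly one quadrant: counts conserve
  qd <- quadrant_dyad_counts(a)
  expect_equal(sum(qd$n), length(a) - 1)
})

test_that("quadrant dyads count consecutive gamma pairs", {
  qd <- quadrant_dyad_counts(c(120, 120))
  expect_equal(qd$n[qd$pattern == "(+B,+B)"], 1)
  expect_equal(sum(qd$n), 1)
  qd2 <- quadrant_dyad_counts(c(120, -120))
  expect_equal(qd2$n[qd2$pattern == "(+B,-B)"], 1)
  expect_equal(sum(quadrant_dyad_counts(55)$n), 0)
  expect_equal(nrow(qd), 16)
})

test_that("histograms are left-closed with +180 in the top bin", {
  h <- angle_histogram(15, bin_width = 10)
  expect_equal(h$n[h$bin_start == 10], 1)
  expect_equal(sum(h$n), 1)
  h2 <- angle_histogram(180, bin_width = 10)
  expect_equal(h2$n[h2$bin_start == 170], 1)
  h3 <- angle_histogram(numeric(0))
  expect_equal(sum(h3$n), 0)
  expect_equal(nrow(h3), 36)
  expect_error(angle_histogram(0, bin_width = 7), class = "bj_bad_config")
  # exhaustiveness at boundary values
  a <- c(-179.999, -90, 0, 90, 179.999, 180)
  expect_equal(sum(angle_histogram(a, 30)$n), length(a))
})

test_that("pattern counts conserve window totals per structure", {
  set.seed(11)
  specs <- c(4, 8, 12, 5)
  descs <- dplyr::bind_rows(lapply(seq_along(specs), function(i) {
    b <- generate_barrel(barrel_spec(specs[i], jitter = 0.05, seed = i))
    descriptor_of(b, structure_id = paste0("s", i))
  }))
  ps <- pattern_summary(descs)
  ec <- expected_counts(specs)
  expect_equal(sum(ps$dyads$n[ps$dyads$type == "beta"]),
               sum(pmax(ec$n_beta - 1, 0)))
  expect_equal(sum(ps$dyads$n[ps$dyads$type == "gamma"]),
               sum(pmax(ec$n_gamma - 1, 0)))
  expect_equal(sum(ps$triads$n[ps$triads$type == "beta"]),
               sum(pmax(ec$n_beta - 2, 0)))
  expect_equal(sum(ps$gamma_quadrant_dyads$n),
               sum(pmax(ec$n_gamma - 1, 0)))
  expect_equal(sum(ps$histograms$n), sum(ec$n_beta) + sum(ec$n_gamma))
})

test_that("negating all angles exchanges mirror-dual patterns", {
  set.seed(13)
  b <- generate_barrel(barrel_spec(12, jitter = 0.04, seed = 3))
  d <- descriptor_of(b, structure_id = "x")
  dm <- d
  dm$angle <- -dm$angle
  dm$angle[dm$angle <= -180] <- dm$angle[dm$angle <= -180] + 360
  ps <- pattern_summary(d)$dyads
  pm <- pattern_summary(dm)$dyads
  for (ty in c("beta", "gamma")) {
    a <- ps[ps$type == ty, ]; b2 <- pm[pm$type == ty, ]
    expect_equal(a$n[a$pattern == "(+,+)"], b2$n[b2$pattern == "(-,-)"])
    expect_equal(a$n[a$pattern == "(+,-)"], b2$n[b2$pattern == "(-,+)"])
  }
})

test_that("grouping schemes bin structures by strand count", {
  expect_equal(names(tm_scheme()$bins), c("4-10", "12-16", "18-26"))
  expect_true(19 %in% tm_scheme()$bins[["18-26"]])
  expect_equal(names(cyto_scheme()$bins), c("4-6", "7-8", "10-14"))
  expect_error(grouping_scheme("bad", list(a = 1:3, b = 3:5)),
               class = "bj_bad_config")
})

test_that("aggregation sums counts per group and never crosses structures", {
  # two 4-strand structures with beta signs "+++" and "++-"
  b1 <- generate_barrel(barrel_spec(4))             # all positive
  d1 <- descriptor_of(b1, structure_id = "a")
  d2 <- descriptor_of(b1, structure_id = "b")
  d2$angle[d2$label == "beta_3"] <- -15
  ag <- aggregate_patterns(dplyr::bind_rows(d1, d2), tm_scheme())
  bd <- ag$group_dyads[ag$group_dyads$type == "beta", ]
  expect_equal(unique(bd$group), "4-10")
  expect_equal(bd$n[bd$pattern == "(+,+)"], 3)   # 2 from "a", 1 from "b"
  expect_equal(bd$n[bd$pattern == "(+,-)"], 1)
  expect_equal(sum(bd$n), 4)                     # no cross-structure dyads

  # a structure outside every bin is excluded with a warning
  d11 <- descriptor_of(generate_barrel(barrel_spec(11)),
                       structure_id = "outside")
  expect_warning(
    ag2 <- aggregate_patterns(dplyr::bind_rows(d1, d11), tm_scheme()),
    class = "bj_outside_scheme")
  expect_false("outside" %in% ag2$positions$structure_id)
})

test_that("mixed strand counts map to their scheme groups", {
  descs <- dplyr::bind_rows(lapply(c(4, 12, 22), function(n) {
    descriptor_of(generate_barrel(barrel_spec(n)),
                  structure_id = paste0("n", n))
  }))
  ag <- aggregate_patterns(descs, tm_scheme())
  got <- unique(ag$positions[, c("structure_id", "group")])
  expect_equal(got$group[match(c("n4", "n12", "n22"), got$structure_id)],
               c("4-10", "12-16", "18-26"))
})
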