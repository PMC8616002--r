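test_that("pH grids have floor((max-min)/step)+1 values and respect bounds", {
  expect_length(build_ph_grid(0, 14, 0.5)$values, 29)
  expect_identical(build_ph_grid(7, 7, 0.5)$values, 7)
  expect_length(build_ph_grid(0, 14, 1.0)$values, 15)
  g <- build_ph_grid(2.3, 9.1, 0.7)
  expect_true(all(diff(g$values) > 0))
  expect_lte(max(g$values), 9.1)
  expect_error(build_ph_grid(8, 2), "ph_min")
  expect_error(build_ph_grid(0, 14, 0), "step")
  expect_error(build_ph_grid(-1, 5, 1), "pH")
})

test_that("grid count matches brute-force enumeration on random triples", {
  set.seed(19)
  for (i in 1:1000) {
    lo <- round(stats::runif(1, 0, 13), 2)
    hi <- round(stats::runif(1, lo, 14), 2)
    step <- round(stats::runif(1, 0.05, 3), 2)
    if (hi <= lo) next
    n <- length(build_ph_grid(lo, hi, step)$values)
    # enumerate lo, lo+step, ... while <= hi (same 1e-9 slack as the grid)
    k <- 0L; v <- lo
    while (v <= hi + 1e-9 * step) { k <- k + 1L; v <- lo + k * step }
    expect_identical(n, k)
  }
})

test_that("scanning produces one point per grid pH with consistent columns", {
  g <- build_ph_grid(0, 14, 1)
  prof <- scan_sequence(strrep("G", 50), g)
  expect_s3_class(prof, "ph_profile")
  expect_identical(prof$ph, g$values)
  # pH-inert control: flat score
  expect_equal(diff(range(prof$score)), 0, tolerance = 1e-12)
  # poly-K titration: NCPR strictly decreasing from ~+1 toward 0
  profK <- scan_sequence(strrep("K", 50), g)
  expect_true(all(diff(profK$ncpr) < 0))
  expect_gt(profK$ncpr[1], 0.999)
  expect_lt(profK$ncpr[length(g$values)], 0.001)
  oracle <- vapply(g$values, function(p) ncpr_oracle(strrep("K", 50), p),
                   numeric(1))
  expect_equal(profK$ncpr, oracle, tolerance = 1e-12)
  # degenerate single-pH grid
  p1 <- scan_sequence("MKV", build_ph_grid(7, 7, 0.5))
  expect_identical(nrow(p1), 1L)
  # state labels always agree with the score sign
  expect_identical(profK$state, ifelse(profK$score > 0, "folded", "unfolded"))
})

# wrap a raw score series in a minimal ph_profile for rule-level tests
fake_profile <- function(scores, id = "fake") {
  ph <- if (length(scores) == 1L) 7 else seq(0, 14, length.out = length(scores))
  structure(
    data.frame(ph = ph, mean_h = 0.5, ncpr = 0, score = scores,
               state = ifelse(scores > 0, "folded", "unfolded")),
    class = c("ph_profile", "data.frame"), id = id)
}

test_that("transition detection applies the band gate and debouncing rules", {
  # one disorder-to-order crossing
  r1 <- detect_transitions(fake_profile(c(-0.5, -0.2, 0.1, 0.4)))
  expect_identical(r1$verdict, "transition")
  expect_identical(r1$transitions$direction, "conditional folding")
  # interpolated zero between the 2nd and 3rd grid points
  step <- 14 / 3
  expect_equal(r1$transitions$ph, step + 0.2 / 0.3 * step, tolerance = 1e-12)
  # a pair entirely inside the band is not a transition
  expect_warning(
    r2 <- detect_transitions(fake_profile(c(-0.015, 0.015))),
    "low-confidence")
  expect_identical(r2$verdict, "unfolded")
  expect_identical(nrow(r2$transitions), 0L)
  # two sign flips make a multitransition, folding then unfolding
  r3 <- detect_transitions(fake_profile(c(-0.5, 0.5, -0.5)))
  expect_identical(r3$verdict, "multitransition")
  expect_identical(r3$transitions$direction,
                   c("conditional folding", "conditional unfolding"))
  expect_true(all(diff(r3$transitions$ph) > 0))
  # in-band wiggles between definite signs are debounced
  r4 <- detect_transitions(fake_profile(c(-0.5, 0.01, -0.01, 0.01, 0.5)))
  expect_identical(r4$verdict, "transition")
  # extrema and their pH positions are reported
  expect_equal(r3$max_score, 0.5)
  expect_equal(r3$min_score, -0.5)
  expect_gte(r3$max_score, r3$min_score)
  # single-point profiles never transition
  r5 <- detect_transitions(fake_profile(0.4))
  expect_identical(r5$verdict, "folded")
})

test_that("crossing parity matches the endpoint band signs (seeded fuzzer)", {
  set.seed(101)
  n_checked <- 0
  for (i in 1:2000) {
    n <- sample(2:40, 1)
    scores <- round(stats::runif(n, -1, 1), 3)
    prof <- fake_profile(scores)
    rep <- suppressWarnings(detect_transitions(prof, ci = 0.02))
    band <- ifelse(scores > 0.02, 1L, ifelse(scores < -0.02, -1L, 0L))
    nz <- band[band != 0]
    k <- nrow(rep$transitions)
    if (length(nz) == 0) {
      expect_identical(k, 0L)
    } else {
      gate <- max(scores) > 0.02 && min(scores) < -0.02
      if (!gate) expect_identical(k, 0L)
      else expect_identical(k %% 2L == 1L, nz[1] != nz[length(nz)])
      n_checked <- n_checked + 1
    }
    # consecutive transitions always alternate direction
    if (k > 1) {
      expect_true(all(rep$transitions$direction[-1] !=
                        rep$transitions$direction[-k]))
    }
    # crossings stay inside the grid
    if (k > 0) {
      expect_true(all(rep$transitions$ph >= min(prof$ph) &
                        rep$transitions$ph <= max(prof$ph)))
    }
  }
  expect_gt(n_checked, 1000)
})

test_that("sub-band perturbations never flip a definite sign", {
  # scores outside the band by more than the perturbation keep their sign,
  # so the gate and the flip count are stable
  set.seed(55)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    base <- sample(c(-1, 1), n, replace = TRUE) *
      stats::runif(n, 0.05, 1)  # all well outside +/-0.02
    eps <- stats::runif(n, -0.019, 0.019)
    r0 <- detect_transitions(fake_profile(base))
    r1 <- detect_transitions(fake_profile(base + eps))
    expect_identical(r1$verdict, r0$verdict)
    expect_identical(nrow(r1$transitions), nrow(r0$transitions))
  }
})

test_that("crossing pH classes split at 6 and 8 with a closed neutral interval", {
  expect_identical(classify_transition_ph(5.9), "acid")
  expect_identical(classify_transition_ph(6.0), "neutral")
  expect_identical(classify_transition_ph(8.0), "neutral")
  expect_identical(classify_transition_ph(8.5), "basic")
  expect_identical(classify_transition_ph(c(0, 7, 14)),
                   c("acid", "neutral", "basic"))
})

test_that("dataset summaries count verdicts, directions and crossings", {
  mk_report <- function(id, scores) {
    suppressWarnings(detect_transitions(fake_profile(scores, id)))
  }
  # none transitioning
  flat <- lapply(1:10, function(i) mk_report(paste0("f", i), c(0.3, 0.4)))
  s0 <- summarize_scan(flat)
  expect_identical(s0$n_no_transition, 10L)
  expect_equal(s0$pct_no_transition, 100)
  # mixed: 2 none, 1 single folding, 1 multi (folding first)
  reps <- list(
    mk_report("a", c(0.3, 0.4)),
    mk_report("b", c(-0.3, -0.4)),
    mk_report("c", c(-0.5, -0.2, 0.1, 0.4)),   # folding, crossing pH < 6
    mk_report("d", c(-0.5, 0.5, -0.5))          # multi, folding first
  )
  s1 <- summarize_scan(reps)
  expect_identical(s1$n_no_transition, 2L)
  expect_identical(s1$n_single_transition, 1L)
  expect_identical(s1$n_multitransition, 1L)
  expect_equal(s1$pct_transition, 50)
  expect_equal(s1$pct_single_of_transitioning, 50)
  expect_equal(s1$pct_multi_of_transitioning, 50)
  expect_equal(s1$pct_conditional_folding, 100)
  expect_identical(s1$n_crossings, 3L)
  # percentages always normalize
  expect_equal(s1$pct_no_transition + s1$pct_transition, 100,
               tolerance = 0.1)
  expect_equal(s1$pct_single_of_transitioning +
                 s1$pct_multi_of_transitioning, 100, tolerance = 0.1)
  expect_equal(s1$pct_acid + s1$pct_neutral + s1$pct_basic, 100,
               tolerance = 0.1)
  expect_error(summarize_scan(list()), "no reports")
})

test_that("designed copolymers cross near their titrating residue's pKa", {
  g <- build_ph_grid(0, 14, 0.5)
  cases <- list(
    list(rec = make_fixture("alternating", c("V", "K"), 25),
         dir = "conditional folding", pka = default_pka("K")),
    list(rec = make_fixture("alternating", c("V", "E"), 25),
         dir = "conditional unfolding", pka = default_pka("E"))
  )
  for (cs in cases) {
    rep <- detect_transitions(scan_sequence(cs$rec, g))
    expect_identical(rep$verdict, "transition")
    expect_identical(rep$transitions$direction, cs$dir)
    expect_lt(abs(rep$transitions$ph - cs$pka), 2)
    # halving the step keeps the verdict and moves the crossing by less
    # than one coarse step
    rep2 <- detect_transitions(
      scan_sequence(cs$rec, build_ph_grid(0, 14, 0.25)))
    expect_identical(rep2$verdict, "transition")
    expect_identical(rep2$transitions$direction, cs$dir)
    expect_lt(abs(rep2$transitions$ph - rep$transitions$ph), 0.5)
  }
  # the histidine copolymer crosses in the physiological window
  repH <- detect_transitions(
    scan_sequence(make_fixture("alternating", c("V", "H"), 25), g))
  expect_identical(repH$transitions$direction, "conditional folding")
  expect_gte(repH$transitions$ph, 6)
  expect_lte(repH$transitions$ph, 8)
})
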