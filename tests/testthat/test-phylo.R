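test_that("newick parsing flags polytomies and rejects defects", {
  tr <- parseNewick("((A:1,B:1):1,C:2);")
  expect_equal(length(tr$tip.label), 3)
  expect_equal(tr$Nnode, 2)
  expect_false(attr(tr, "polytomy"))

  poly <- parseNewick("((A:1,B:1,C:1):1,D:1);")
  expect_true(attr(poly, "polytomy"))

  expect_error(parseNewick("(A:1,B);"), "branch length")
  expect_error(parseNewick("((A:1,B:1:2,C);"), "malformed|branch")
  expect_error(parseNewick("(A:1,A:1);"), "duplicate leaf")
})

test_that("zero branches take half the shortest positive length", {
  tr <- parseNewick("((A:0,B:0.00006):0.5,C:0.5);")
  adj <- adjustZeroBranches(tr)
  expect_equal(min(adj$edge.length), 0.00003)

  tr2 <- parseNewick("(A:0,B:1);")
  expect_equal(min(adjustZeroBranches(tr2)$edge.length), 0.5)

  tr3 <- parseNewick("(A:1,B:2);")
  expect_identical(adjustZeroBranches(tr3)$edge.length, tr3$edge.length)

  expect_equal(min(adjustZeroBranches(tr2, "fixed", value = 0.1)$edge.length),
               0.1)
  tr0 <- tr2; tr0$edge.length[] <- 0
  expect_error(adjustZeroBranches(tr0), "all branches")
})

test_that("contrasts match closed forms and the hand-run recursion", {
  two <- parseNewick("(A:1,B:1);")
  expect_equal(unname(contrastValues(independentContrasts(two, c(A = 2, B = 0)))),
               2 / sqrt(2))

  three <- parseNewick("((A:1,B:1):1,C:2);")
  cs <- contrastValues(independentContrasts(three, c(A = 3, B = 1, C = 0)))
  expect_equal(sort(unname(cs)), sort(unname(THREE_LEAF_CONTRASTS)),
               tolerance = 1e-12)

  ## constant trait: all contrasts zero
  cs0 <- contrastValues(independentContrasts(three, c(A = 5, B = 5, C = 5)))
  expect_equal(unname(cs0), c(0, 0))

  expect_error(independentContrasts(three, c(A = 1, B = 2)), "species: C")
})

test_that("contrasts agree with an independent implementation on random trees", {
  set.seed(21)
  for (n in c(4, 7, 12)) {
    tr <- ape::rtree(n)
    trait <- setNames(rnorm(n, 10, 4), tr$tip.label)
    ours <- contrastValues(independentContrasts(tr, trait))
    ref <- ape::pic(trait[tr$tip.label], tr)
    expect_equal(length(ours), n - 1)
    expect_equal(sort(abs(unname(ours))), sort(abs(unname(ref))),
                 tolerance = 1e-9)
  }
})

test_that("relabeling children flips contrast signs but not |c| or R", {
  trait <- c(A = 3, B = 1, C = 0)
  t1 <- parseNewick("((A:1,B:1):1,C:2);")
  t2 <- parseNewick("((B:1,A:1):1,C:2);")
  c1 <- independentContrasts(t1, trait)
  c2 <- independentContrasts(t2, trait)
  expect_equal(sort(abs(contrastValues(c1))), sort(abs(contrastValues(c2))),
               ignore_attr = TRUE)
  trait2 <- c(A = 1, B = 5, C = 2)
  d1 <- independentContrasts(t1, trait2)
  d2 <- independentContrasts(t2, trait2)
  expect_equal(contrastCorrelation(c1, d1), contrastCorrelation(c2, d2))
})

test_that("through-origin correlation behaves at its boundary cases", {
  expect_equal(contrastCorrelation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(contrastCorrelation(c(1, 0), c(0, 1)), 0)
  expect_equal(contrastCorrelation(c(1, 2), c(-1, -2)), -1)
  ## joint sign flips leave R unchanged (positivization is cosmetic)
  expect_equal(contrastCorrelation(c(-1, 2), c(1, -2), positivize = TRUE),
               contrastCorrelation(c(-1, 2), c(1, -2)))
  expect_error(contrastCorrelation(c(0, 0), c(1, 2)), "all-zero")
})

test_that("randomization p respects its bounds and the plus-one arithmetic", {
  set.seed(9)
  x <- rnorm(12); y <- rnorm(12)
  for (seed in 1:5) {
    r <- randomizationPvalue(x, y, nPerm = 99, seed = seed)
    expect_gte(pValue(r), 1 / 100)
    expect_lte(pValue(r), 1)
    expect_equal(pValue(r), (exceedances(r) + 1) / 100)
  }
  ## near-perfect association: p at (or near) the lower bound
  r2 <- randomizationPvalue(1:10, 1:10 + rnorm(10, 0, 1e-3),
                            nPerm = 199, seed = 4)
  expect_lte(pValue(r2), 3 / 200)
  ## same seed, same result
  expect_identical(
    exceedances(randomizationPvalue(x, y, nPerm = 99, seed = 7)),
    exceedances(randomizationPvalue(x, y, nPerm = 99, seed = 7)))
})

test_that("the randomization test is calibrated under an independent null", {
  ## the exceedance is one-sided in the direction of the observed R, so under
  ## independence p behaves like the smaller of two tails: approximately
  ## uniform on (0, 1/2], with P(p <= a) ~ 2a for small a
  set.seed(31)
  x <- rnorm(15)
  ps <- vapply(1:200, function(i) {
    y <- rnorm(15)
    pValue(randomizationPvalue(x, y, nPerm = 199, seed = i))
  }, numeric(1))
  expect_gt(mean(ps), 0.17)
  expect_lt(mean(ps), 0.33)
  fp <- mean(ps <= 0.05)
  expect_gt(fp, 0.03)   # ~2 * 0.05 expected
  expect_lt(fp, 0.20)
})

test_that("per-amino-acid profile rejects undersized or mismatched panels", {
  set.seed(2)
  prot <- lapply(1:2, function(i) setNames(randomProtein(200), "p1"))
  names(prot) <- c("a", "b")
  expect_error(
    perAaTemperatureProfile(prot, setNames(c(10, 20), c("a", "b"))),
    "at least 3")

  prot3 <- lapply(1:3, function(i) setNames(randomProtein(200), "p1"))
  names(prot3) <- c("a", "b", "c")
  tr <- parseNewick("((a:1,d:1):1,c:2);")
  expect_error(
    perAaTemperatureProfile(prot3, setNames(c(10, 20, 30), c("a", "b", "c")),
                            tree = tr),
    "mismatch")
})
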