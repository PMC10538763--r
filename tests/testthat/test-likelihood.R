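test_that("mutation kernels match their definitions", {
  expect_equal(mut_prob_str(10, 10, 0.01), 0.99)
  expect_equal(mut_prob_str(10, 11, 0.01), 0.01)
  expect_equal(mut_prob_str(10, 12.5, 0.01), 0)
  expect_equal(mut_prob_str(9.3, 10.3, 0.01), 0.01)  # fractional, exact step
  expect_equal(mut_prob_str(9.3, 10, 0.01), 0)
  expect_equal(mut_prob_poly("A", "G", 0.001), 9e-4)  # transition
  expect_equal(mut_prob_poly("C", "T", 0.001), 9e-4)
  expect_equal(mut_prob_poly("A", "C", 0.001), 1e-4)  # transversion
  expect_equal(mut_prob_poly("A", "A", 0.001), 0.999)
  expect_equal(mut_prob_poly("A", "ACT", 0.001), 1e-4)  # complex change
})

test_that("direct child likelihood reproduces worked examples", {
  p1 <- marker_panel("M1", "STR")
  expect_equal(child_likelihood_direct(10, phased_mother(10, 12),
                                       rate_params(numeric(0), 0.01), p1),
               0.99)
  p2 <- marker_panel(c("M1", "M2"), c("STR", "STR"))
  m <- phased_mother(c(10, 20), c(12, 22))
  expect_equal(child_likelihood_direct(c(10, 20), m,
                                       rate_params(0.1, c(0, 0)), p2), 0.9)
  expect_equal(child_likelihood_direct(c(10, 22), m,
                                       rate_params(0.5, c(0, 0)), p2), 0.5)
})

test_that("dynamic engine equals direct enumeration on random instances", {
  set.seed(101)
  for (r in 1:60) {
    inst <- rand_typeI(sample(1:10, 1), k = 1)
    fam <- inst$fam
    a <- child_likelihood_dynamic(fam$children[[1]], fam$mother,
                                  inst$params, fam$panel)
    b <- child_likelihood_direct(fam$children[[1]], fam$mother,
                                 inst$params, fam$panel)
    expect_lt(rel_diff(a, b), 1e-12)
  }
})

test_that("type I likelihood is the product over children", {
  set.seed(7)
  inst <- rand_typeI(5, k = 1)
  fam <- inst$fam
  single <- child_likelihood_dynamic(fam$children[[1]], fam$mother,
                                     inst$params, fam$panel)
  expect_equal(family_likelihood_typeI(fam, inst$params), single)
  fam2 <- informative_family("typeI", fam$mother,
                             rep(fam$children, 2), fam$panel)
  expect_equal(family_likelihood_typeI(fam2, inst$params), single^2,
               tolerance = 1e-12)
  # haplotype label swap leaves the likelihood unchanged
  fam_sw <- informative_family(
    "typeI", phased_mother(fam$mother$hap2, fam$mother$hap1),
    fam$children, fam$panel)
  expect_equal(family_likelihood_typeI(fam_sw, inst$params),
               family_likelihood_typeI(fam, inst$params), tolerance = 1e-12)
})

test_that("type II pruned likelihood equals exhaustive phasing enumeration", {
  p2 <- marker_panel(c("M1", "M2"), c("STR", "STR"))
  fam <- informative_family("typeII",
                            unphased_mother(rbind(c(10, 20), c(12, 22))),
                            list(c(10, 20), c(12, 22)), p2)
  pr <- rate_params(0.1, c(0, 0))
  expect_equal(family_likelihood_typeII(fam, pr), 0.82, tolerance = 1e-12)
  set.seed(202)
  for (r in 1:25) {
    inst <- rand_typeII(sample(2:8, 1), k = sample(2:3, 1))
    prn <- family_likelihood_typeII(inst$fam, inst$params)
    dir <- family_likelihood_typeII(inst$fam, inst$params, engine = "direct")
    orc <- oracle_typeII(inst$fam, inst$params)
    expect_lt(rel_diff(prn, orc), 1e-12)
    expect_lt(rel_diff(dir, orc), 1e-12)
  }
  # fully homozygous mother: single phasing, equals the type I value
  fam_h <- informative_family("typeII",
                              unphased_mother(rbind(c(10, 20), c(10, 20))),
                              list(c(10, 20), c(10, 21)), p2)
  prm <- rate_params(0.2, c(0.01, 0.01))
  t1 <- informative_family("typeI", phased_mother(c(10, 20), c(10, 20)),
                           fam_h$children, p2)
  expect_equal(family_likelihood_typeII(fam_h, prm),
               family_likelihood_typeI(t1, prm), tolerance = 1e-12)
})

test_that("closed-form limits hold", {
  set.seed(33)
  # theta = 0.5 everywhere: markers decouple
  inst <- rand_typeI(6, k = 1)
  fam <- inst$fam
  pr <- rate_params(rep(0.5, 5), inst$params$mu)
  per_marker <- vapply(1:6, function(i) {
    pstar <- function(m) xrecomb:::pstar_code(m, fam$children[[1]][i],
                                              pr$mu[i], fam$panel$types[i],
                                              fam$panel$bclass[[i]])
    pstar(fam$mother$hap1[i]) + pstar(fam$mother$hap2[i])
  }, 0)
  expect_equal(child_likelihood_dynamic(fam$children[[1]], fam$mother, pr,
                                        fam$panel),
               0.5^5 * prod(per_marker), tolerance = 1e-12)
  # mu = 0, all-heterozygous mother, child = hap1: product of (1 - theta_i)
  n <- 7
  p <- marker_panel(paste0("M", 1:n), rep("STR", n))
  m1 <- rep(10, n); m2 <- rep(12, n)
  th <- runif(n - 1, 0.05, 0.45)
  pr0 <- rate_params(th, rep(0, n))
  lik <- child_likelihood_dynamic(m1, phased_mother(m1, m2), pr0, p)
  expect_equal(lik, prod(1 - th), tolerance = 1e-12)
  expect_equal(child_likelihood_direct(m1, phased_mother(m1, m2), pr0, p),
               prod(1 - th), tolerance = 1e-12)
  # and it is strictly decreasing in each theta_i
  for (i in seq_len(n - 1)) {
    th2 <- th; th2[i] <- min(th[i] + 0.04, 0.5)
    lik2 <- child_likelihood_dynamic(m1, phased_mother(m1, m2),
                                     rate_params(th2, rep(0, n)), p)
    expect_lt(lik2, lik)
  }
})

test_that("missing child markers contribute mutation factor 1", {
  p2 <- marker_panel(c("M1", "M2"), c("STR", "STR"))
  m <- phased_mother(c(10, 20), c(12, 22))
  pr <- rate_params(0.1, c(0, 0))
  expect_equal(child_likelihood_dynamic(c(NA, 20), m, pr, p2), 1)
  expect_equal(child_likelihood_direct(c(NA, 20), m, pr, p2), 1)
  # recombination factors still chain through a missing middle marker
  p3 <- marker_panel(paste0("M", 1:3), rep("STR", 3))
  m3 <- phased_mother(c(10, 20, 30), c(12, 22, 32))
  pr3 <- rate_params(c(0.1, 0.2), rep(0, 3))
  got <- child_likelihood_dynamic(c(10, NA, 32), m3, pr3, p3)
  # switch happened either between 1-2 or 2-3: 0.1*0.8 + 0.9*0.2
  expect_equal(got, 0.1 * 0.8 + 0.9 * 0.2, tolerance = 1e-12)
  expect_equal(child_likelihood_direct(c(10, NA, 32), m3, pr3, p3), got,
               tolerance = 1e-12)
})

test_that("dataset_negloglik adds -log likelihoods and flags zeros", {
  p2 <- marker_panel(c("M1", "M2"), c("STR", "STR"))
  m <- phased_mother(c(10, 20), c(12, 22))
  fam <- informative_family("typeI", m, list(c(10, 20)), p2,
                            provenance = list(family_id = "F1",
                                              mother_id = "MOM"))
  pr <- rate_params(0.1, c(0, 0))
  expect_equal(dataset_negloglik(list(fam), pr), -log(0.9))
  expect_equal(dataset_negloglik(list(fam, fam), pr), -2 * log(0.9))
  # incompatible data (multi-step change) at interior parameters
  bad <- informative_family("typeI", m, list(c(15, 20)), p2,
                            provenance = list(family_id = "F1",
                                              mother_id = "MOM"))
  expect_error(dataset_negloglik(list(bad), rate_params(0.1, c(0.01, 0.01))),
               "F1/MOM")
  # direct and dynamic engines agree on a mixed dataset
  set.seed(55)
  fams <- c(lapply(1:5, function(i) rand_typeI(6)$fam),
            lapply(1:5, function(i) rand_typeII(6)$fam))
  prm <- rate_params(runif(5, 0.01, 0.4), runif(6, 0.001, 0.1))
  expect_equal(dataset_negloglik(fams, prm, engine = "dynamic"),
               dataset_negloglik(fams, prm, engine = "direct"),
               tolerance = 1e-10)
})

test_that("engine guard rails refuse impractical sizes", {
  n <- 30
  p <- marker_panel(paste0("M", 1:n), rep("STR", n))
  m <- phased_mother(rep(10, n), rep(12, n))
  pr <- rate_params(rep(0.1, n - 1), rep(0, n))
  expect_error(child_likelihood_direct(rep(10, n), m, pr, p), "refused")
  fam <- informative_family("typeII",
                            unphased_mother(rbind(rep(10, n), rep(12, n))),
                            list(rep(10, n), rep(12, n)), p)
  expect_error(family_likelihood_typeII(fam, pr), "cap")
  # the dynamic type I path has no such limit
  expect_true(is.finite(child_likelihood_dynamic(rep(10, n), m, pr, p,
                                                 log = TRUE)))
})
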