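test_that("build_family_graphs splits components and validates parents", {
  inds <- c(trio("T1"), trio("T2"))
  graphs <- build_family_graphs(inds)
  expect_length(graphs, 2L)
  expect_length(build_family_graphs(list()), 0L)

  bad <- list(
    x_individual("F1", "P", sex = "female", alleles = rbind(10, 12)),
    x_individual("F1", "K", father_id = "P", sex = "male", alleles = 10))
  expect_error(build_family_graphs(bad), "not male")

  orphanish <- list(
    x_individual("F1", "K", father_id = "GHOST", sex = "male", alleles = 10))
  expect_warning(build_family_graphs(orphanish), "treated as absent")
})

test_that("phase_daughter subtracts the paternal haplotype", {
  panel_n <- 3
  d <- x_individual("F", "D", sex = "female",
                    alleles = rbind(c(10, 10, 10), c(12, 10, 12)))
  f <- x_individual("F", "P", sex = "male", alleles = c(12, 10, 14))
  hap <- phase_daughter(d, f)
  expect_equal(as.numeric(hap[1:2]), c(10, 10))  # subtraction, homozygous
  expect_true(is.na(hap[3]))                     # conflict marker
  expect_equal(attr(hap, "conflicts"), 3L)
})

test_that("phase_mother_by_grandfather recovers both haplotypes", {
  m <- x_individual("F", "M", sex = "female",
                    alleles = rbind(c(10, 10), c(12, 10)))
  gf <- x_individual("F", "G", sex = "male", alleles = c(12, 10))
  pm <- phase_mother_by_grandfather(m, gf)
  expect_equal(pm$hap1, c(12, 10))
  expect_equal(pm$hap2, c(10, 10))
  # re-deriving the genotype from the phase reproduces the input (involution)
  expect_equal(apply(rbind(pm$hap1, pm$hap2), 2, sort), m$alleles)

  gf_bad <- x_individual("F", "G", sex = "male", alleles = c(14, 10))
  expect_warning(expect_null(phase_mother_by_grandfather(m, gf_bad)),
                 "phasing conflict")
})

# a connected pedigree yielding one type I and two type II families:
# GF phases MOM1 (two sons S1, S2); MOM2 and MOM3 marry into the pedigree
# with no genotyped father and two sons each
fig_pedigree <- function() {
  n <- 2
  hap <- function(a) rep(a, n)
  list(
    x_individual("P", "GF", sex = "male", alleles = hap(10)),
    x_individual("P", "MOM1", father_id = "GF", sex = "female",
                 alleles = rbind(hap(10), hap(12))),
    x_individual("P", "S1", mother_id = "MOM1", sex = "male", alleles = hap(10)),
    x_individual("P", "S2", mother_id = "MOM1", sex = "male", alleles = hap(12)),
    x_individual("P", "MOM2", sex = "female", alleles = rbind(hap(14), hap(15))),
    x_individual("P", "N1", father_id = "S1", mother_id = "MOM2", sex = "male",
                 alleles = hap(14)),
    x_individual("P", "N2", father_id = "S1", mother_id = "MOM2", sex = "male",
                 alleles = hap(15)),
    x_individual("P", "MOM3", sex = "female", alleles = rbind(hap(16), hap(17))),
    x_individual("P", "N3", father_id = "S2", mother_id = "MOM3", sex = "male",
                 alleles = hap(16)),
    x_individual("P", "N4", father_id = "S2", mother_id = "MOM3", sex = "male",
                 alleles = hap(17)))
}

test_that("extract_families finds one type I and two type II families", {
  inds <- fig_pedigree()
  graphs <- build_family_graphs(inds)
  expect_length(graphs, 1L)  # fully connected pedigree
  panel <- marker_panel(c("M1", "M2"), c("STR", "STR"))
  fams <- extract_families(graphs, panel)
  expect_length(fams, 3L)
  kinds <- vapply(fams, `[[`, "", "kind")
  expect_equal(sort(kinds), c("typeI", "typeII", "typeII"))
  t1 <- fams[[which(kinds == "typeI")]]
  expect_equal(t1$provenance$mother_id, "MOM1")
  expect_length(t1$children, 2L)
})

test_that("threshold rules: trio gives nothing; son+daughter give type II", {
  panel <- marker_panel(c("M1", "M2"), c("STR", "STR"))
  # lone trio with a single son and no grandfather: not informative
  fams <- suppressMessages(
    extract_families(build_family_graphs(trio("T1", n_sons = 1)), panel))
  expect_length(fams, 0L)
  # mother with one son and one father-genotyped daughter: type II, 2 children
  inds <- trio("T1", n_sons = 1)
  inds[[length(inds) + 1]] <- x_individual(
    "T1", "D1", father_id = "DAD", mother_id = "MOM", sex = "female",
    alleles = rbind(c(14, 14), c(12, 10)))
  fams <- extract_families(build_family_graphs(inds), panel)
  expect_length(fams, 1L)
  expect_equal(fams[[1]]$kind, "typeII")
  expect_length(fams[[1]]$children, 2L)
  # daughter phased by subtraction of DAD's (14, 14); children sorted by ID
  expect_equal(fams[[1]]$provenance$child_ids, c("D1", "S1"))
  expect_equal(fams[[1]]$children[[1]], c(12, 10))
})

test_that("conflicts downgrade or drop instead of failing silently", {
  panel <- marker_panel(c("M1", "M2"), c("STR", "STR"))
  # grandfather conflicting with the mother: phase voided, type II still forms
  inds <- trio("T1", n_sons = 2)
  inds[[length(inds) + 1]] <- x_individual("T1", "GF", sex = "male",
                                           alleles = c(18, 18))
  inds[[2]]$father_id <- "GF"
  expect_warning(
    fams <- extract_families(build_family_graphs(inds), panel),
    "phasing conflict")
  expect_length(fams, 1L)
  expect_equal(fams[[1]]$kind, "typeII")
  # conflicting daughter is excluded from the children set
  inds2 <- trio("T2", n_sons = 2)
  inds2[[length(inds2) + 1]] <- x_individual(
    "T2", "D1", father_id = "DAD", mother_id = "MOM", sex = "female",
    alleles = rbind(c(19, 10), c(19, 12)))  # DAD carries 14: conflict at M1
  expect_warning(
    fams2 <- extract_families(build_family_graphs(inds2), panel),
    "daughter excluded")
  expect_length(fams2[[1]]$children, 2L)
})

test_that("mothers with missing genotypes are skipped with a log line", {
  panel <- marker_panel(c("M1", "M2"), c("STR", "STR"))
  inds <- trio("T1", n_sons = 2)
  inds[[2]]$alleles[, 1] <- NA
  expect_message(
    fams <- extract_families(build_family_graphs(inds), panel),
    "missing genotype")
  expect_length(fams, 0L)
})

test_that("extraction is deterministic and order-independent", {
  sim <- simulate_pedigrees(sim_config(n_markers = 4, n_typeI = 6,
                                       n_typeII = 6, seed = 11))
  graphs <- build_family_graphs(sim$individuals)
  fams <- extract_families(graphs, sim$panel)
  set.seed(99)
  shuffled <- sim$individuals[sample(length(sim$individuals))]
  fams2 <- extract_families(build_family_graphs(shuffled), sim$panel)
  expect_equal(fams, fams2)
})

test_that("extraction recovers simulated truth exactly (no mutations)", {
  sim <- simulate_pedigrees(sim_config(n_markers = 5, theta_true = 0.2,
                                       mu_true = 0, n_typeI = 10,
                                       n_typeII = 10, seed = 5))
  fams <- extract_families(build_family_graphs(sim$individuals), sim$panel)
  expect_length(fams, 20L)
  for (fam in fams) {
    tr <- sim$truth[[fam$provenance$family_id]]
    expect_equal(fam$kind, tr$kind)
    for (i in seq_along(fam$children)) {
      cid <- fam$provenance$child_ids[i]
      expect_equal(fam$children[[i]], tr$children[[cid]]$maternal_hap)
    }
    if (fam$kind == "typeI") {
      # recovered phase equals the simulated phase up to haplotype labels
      expect_true(
        (identical(fam$mother$hap1, tr$m1) && identical(fam$mother$hap2, tr$m2)) ||
        (identical(fam$mother$hap1, tr$m2) && identical(fam$mother$hap2, tr$m1)))
    }
  }
})
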