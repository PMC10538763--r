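# Random likelihood instances built directly (no PED round trip), plus a
# naive type II oracle that enumerates ordered phasings exhaustively and
# deduplicates by halving (haplotype relabeling is a fixed-point-free
# involution on ordered phasings when h >= 1).

poly_map4 <- function() stats::setNames(-(1:4), c("A", "G", "C", "T"))

rand_panel <- function(n, p_poly = 0.3) {
  types <- ifelse(stats::runif(n) < p_poly, "POLY", "STR")
  maps <- lapply(types, function(t) if (t == "POLY") poly_map4() else NULL)
  marker_panel(paste0("M", seq_len(n)), types, maps)
}

rand_allele <- function(type) {
  if (type == "STR") {
    sample(8:20, 1) + sample(c(0, 0.3), 1, prob = c(0.8, 0.2))
  } else {
    sample(-(1:4), 1)
  }
}

rand_hap <- function(panel) {
  vapply(panel$types, rand_allele, 0, USE.NAMES = FALSE)
}

# meiosis + single-step mutation so instances always have positive likelihood
rand_child_hap <- function(m1, m2, theta, mu, panel) {
  n <- panel$n_markers
  v <- integer(n)
  v[1] <- sample(1:2, 1)
  if (n > 1) {
    for (i in 2:n) {
      v[i] <- if (stats::runif(1) < theta[i - 1]) 3L - v[i - 1] else v[i - 1]
    }
  }
  hap <- ifelse(v == 1L, m1, m2)
  for (j in seq_len(n)) {
    if (stats::runif(1) < mu[j]) {
      if (panel$types[j] == "STR") {
        hap[j] <- hap[j] + sample(c(-1, 1), 1)
      } else {
        hap[j] <- sample(setdiff(-(1:4), hap[j]), 1)
      }
    }
  }
  hap
}

rand_rates <- function(n) {
  rate_params(stats::runif(max(n - 1, 0), min = 1e-4, max = 0.5),
              stats::runif(n, min = 1e-4, max = 0.5))
}

rand_typeI <- function(n, k = 2, p_poly = 0.3) {
  panel <- rand_panel(n, p_poly)
  m1 <- rand_hap(panel); m2 <- rand_hap(panel)
  pr <- rand_rates(n)
  kids <- replicate(k, rand_child_hap(m1, m2, pr$theta, pr$mu, panel),
                    simplify = FALSE)
  list(fam = informative_family("typeI", phased_mother(m1, m2), kids, panel),
       params = pr)
}

rand_typeII <- function(n, k = 2, p_poly = 0.3) {
  panel <- rand_panel(n, p_poly)
  m1 <- rand_hap(panel); m2 <- rand_hap(panel)
  pr <- rand_rates(n)
  kids <- replicate(k, rand_child_hap(m1, m2, pr$theta, pr$mu, panel),
                    simplify = FALSE)
  list(fam = informative_family("typeII", unphased_mother(rbind(m1, m2)),
                                kids, panel),
       params = pr)
}

# Exhaustive type II oracle: sum the type I likelihood over all 2^h ordered
# phasings of the heterozygous markers, then halve (unordered phasings).
oracle_typeII <- function(fam, params) {
  g <- fam$mother$genotype
  het <- which(fam$mother$het_mask)
  h <- length(het)
  total <- 0
  for (b in seq_len(2^h) - 1L) {
    h1 <- g[1L, ]; h2 <- g[2L, ]
    if (h > 0) {
      bits <- bitwAnd(bitwShiftR(b, seq_len(h) - 1L), 1L)
      sw <- het[bits == 1L]
      h1[sw] <- g[2L, sw]; h2[sw] <- g[1L, sw]
    }
    lk <- 1
    for (ch in fam$children) {
      lk <- lk * child_likelihood_direct(ch, phased_mother(h1, h2),
                                         params, fam$panel)
    }
    total <- total + lk
  }
  if (h >= 1) total / 2 else total
}

rel_diff <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.xmin)

# small deterministic pedigree builders -----------------------------------

trio <- function(fid = "T1", n_sons = 1, panel_n = 2) {
  inds <- list(
    x_individual(fid, "DAD", sex = "male", alleles = rep(14, panel_n)),
    x_individual(fid, "MOM", sex = "female",
                 alleles = rbind(rep(10, panel_n), rep(12, panel_n))))
  for (s in seq_len(n_sons)) {
    inds[[length(inds) + 1]] <- x_individual(
      fid, paste0("S", s), father_id = "DAD", mother_id = "MOM",
      sex = "male", alleles = rep(10, panel_n))
  }
  inds
}
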