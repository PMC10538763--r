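#' Simulation configuration
#'
#' Describes the synthetic world of the pedigree simulator: the marker panel,
#' the true rates, and the family structure. Defaults model a typical
#' forensic X-STR validation dataset: STR markers with repeat counts drawn
#' uniformly from 8–20, recombination 0.05 per interval, mutation 0.001 per
#' marker per meiosis (the order observed for forensic STRs), two children
#' per family and an even sex ratio.
#'
#' @param n_markers number of markers.
#' @param marker_types per-marker `"STR"`/`"POLY"` (recycled).
#' @param theta_true true recombination rates, length `n_markers - 1`
#'   (a scalar is broadcast).
#' @param mu_true true mutation rates, length `n_markers` (scalar broadcast).
#' @param n_typeI,n_typeII family counts.
#' @param children_per_family children per family (must be >= 2 when type II
#'   families are requested, or they would not be informative).
#' @param p_daughter probability a child is female.
#' @param str_range integer range `c(lo, hi)` of STR repeat counts.
#' @param poly_alleles allele strings for POLY markers (>= 2).
#' @param include_fathers genotype and emit a father for families with
#'   daughters (required for daughters to be phaseable); disable to exercise
#'   the unphaseable-daughter path.
#' @param missing_rate per individual-marker probability of masking the
#'   genotype as missing (default 0).
#' @param seed RNG seed; identical seeds give byte-identical PED output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_markers = 10L,
                       marker_types = "STR",
                       theta_true = 0.05,
                       mu_true = 0.001,
                       n_typeI = 50L, n_typeII = 50L,
                       children_per_family = 2L,
                       p_daughter = 0.5,
                       str_range = c(8L, 20L),
                       poly_alleles = c("A", "G"),
                       include_fathers = TRUE,
                       missing_rate = 0,
                       seed = 1L) {
  n <- as.integer(n_markers)
  if (n < 1L) stop("need at least one marker")
  types <- rep_len(as.character(marker_types), n)
  if (!all(types %in% c("STR", "POLY"))) stop("marker_types must be STR/POLY")
  theta <- rep_len(as.numeric(theta_true), max(n - 1L, 0L))
  mu <- rep_len(as.numeric(mu_true), n)
  if (any(theta < 0 | theta > 0.5) || any(mu < 0 | mu > 0.5)) {
    stop("theta_true and mu_true must lie in [0, 0.5]")
  }
  if (length(poly_alleles) < 2L && any(types == "POLY")) {
    stop("config error: POLY markers need an allele pool of at least 2")
  }
  if (n_typeII > 0L && children_per_family < 2L) {
    stop("type II families need children_per_family >= 2 to be informative")
  }
  if (children_per_family < 1L) stop("children_per_family must be >= 1")
  structure(list(
    n_markers = n, marker_types = types, theta_true = theta, mu_true = mu,
    n_typeI = as.integer(n_typeI), n_typeII = as.integer(n_typeII),
    children_per_family = as.integer(children_per_family),
    p_daughter = p_daughter, str_range = as.integer(str_range),
    poly_alleles = as.character(poly_alleles),
    include_fathers = isTRUE(include_fathers),
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

# Allele pools on the internal code scale. STR pool: integer repeat counts;
# POLY pool: negative codes (provisional; canonicalized after generation).
sim_pools <- function(config) {
  lapply(seq_len(config$n_markers), function(j) {
    if (config$marker_types[j] == "STR") {
      as.numeric(seq(config$str_range[1], config$str_range[2]))
    } else {
      as.numeric(-seq_along(config$poly_alleles))
    }
  })
}

draw_haplotype <- function(pools) {
  vapply(pools, function(p) p[sample.int(length(p), 1L)], 0)
}

# Sample an inheritance vector: uniform initial state, switch between
# adjacent markers with probability theta_i.
draw_inheritance <- function(n, theta) {
  v <- integer(n)
  v[1] <- sample(1:2, 1L)
  if (n > 1L) {
    flip <- stats::runif(n - 1L) < theta
    for (i in 2:n) v[i] <- if (flip[i - 1L]) 3L - v[i - 1L] else v[i - 1L]
  }
  v
}

# Mutate one haplotype in place according to the marker kernels.
# STR: step up or down one repeat, each with probability mu; a step leaving
# the representable pool is redirected inward, so the total per-marker
# mutation mass is 2*mu everywhere. POLY: each candidate allele b gets mass
# 0.9*mu (transition from the current allele) or 0.1*mu (otherwise); when
# only one alternative exists it receives the full mu mass (the 9:1 split
# needs >= 2 alternatives).
mutate_haplotype <- function(hap, config, pools, bclass) {
  n <- config$n_markers
  mutated <- logical(n)
  for (j in seq_len(n)) {
    mu <- config$mu_true[j]
    if (mu == 0) next
    a <- hap[j]
    if (config$marker_types[j] == "STR") {
      u <- stats::runif(1)
      if (u < 2 * mu) {
        step <- if (u < mu) -1 else 1
        b <- a + step
        if (b < config$str_range[1] || b > config$str_range[2]) b <- a - step
        hap[j] <- b
        mutated[j] <- TRUE
      }
    } else {
      cand <- setdiff(pools[[j]], a)
      if (length(cand) == 1L) {
        w <- 1
      } else {
        w <- ifelse(is_transition_class(bclass[[j]][-a], bclass[[j]][-cand]),
                    0.9, 0.1)
      }
      p <- mu * w
      u <- stats::runif(1)
      cum <- cumsum(p)
      hit <- which(u < cum)
      if (length(hit)) {
        hap[j] <- cand[hit[1]]
        mutated[j] <- TRUE
      }
    }
  }
  list(hap = hap, mutated = mutated)
}

#' Simulate pedigrees with known recombination and mutation rates
#'
#' For each family, the mother's two haplotypes are drawn with independent
#' random alleles; each child's maternal haplotype is produced by drawing an
#' inheritance vector (uniform initial state, switch between adjacent markers
#' with probability `theta_i`), copying the inherited alleles and applying
#' the mutation kernels with rates `mu_i`. Daughters additionally receive a
#' randomly generated father's haplotype (fathers are genotyped and emitted
#' so daughters are phaseable). Type I families add the maternal grandfather
#' carrying one of the mother's haplotypes. Female genotypes are stored as
#' sorted unordered pairs, erasing phase, which preprocessing must recover.
#'
#' @param config a [sim_config()].
#' @return A list of class `xrecomb_sim` with elements `individuals` (list of
#'   [x_individual()]), `panel` (a [marker_panel()] whose POLY codes follow
#'   first-appearance order in the output, so a write/parse round trip is the
#'   identity), `truth` (per family: true mother haplotypes, per child the
#'   inheritance vector, mutation flags and maternal haplotype) and `config`.
#' @export
simulate_pedigrees <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_markers
  pools <- sim_pools(config)
  prov_maps <- lapply(seq_len(n), function(j) {
    if (config$marker_types[j] == "POLY") {
      stats::setNames(-seq_along(config$poly_alleles), config$poly_alleles)
    } else NULL
  })
  prov_bclass <- lapply(seq_len(n), function(j) {
    if (config$marker_types[j] == "POLY") {
      base_class(config$poly_alleles)
    } else integer(0)
  })

  individuals <- list()
  truth <- list()
  add <- function(ind) individuals[[length(individuals) + 1L]] <<- ind

  total <- config$n_typeI + config$n_typeII
  kinds <- rep(c("typeI", "typeII"), c(config$n_typeI, config$n_typeII))
  for (k in seq_len(total)) {
    fid <- sprintf("F%04d", k)
    kind <- kinds[k]
    m1 <- draw_haplotype(pools)
    m2 <- draw_haplotype(pools)
    nk <- config$children_per_family
    sexes <- ifelse(stats::runif(nk) < config$p_daughter, "female", "male")
    # daughters always carry a paternal haplotype; the father individual is
    # only emitted (making daughters phaseable) when include_fathers is set
    father_hap <- if (any(sexes == "female")) draw_haplotype(pools) else NULL
    need_father <- config$include_fathers && any(sexes == "female")

    mom_father_id <- if (kind == "typeI") "GF" else NA
    if (kind == "typeI") {
      gf_hap <- if (stats::runif(1) < 0.5) m1 else m2
      add(x_individual(fid, "GF", sex = "male", alleles = gf_hap))
    }
    if (need_father) {
      add(x_individual(fid, "DAD", sex = "male", alleles = father_hap))
    }
    add(x_individual(fid, "MOM", father_id = mom_father_id, sex = "female",
                     alleles = rbind(m1, m2)))

    fam_truth <- list(family_id = fid, kind = kind, m1 = m1, m2 = m2,
                      children = list())
    for (ci in seq_len(nk)) {
      cid <- sprintf("C%02d", ci)
      v <- draw_inheritance(n, config$theta_true)
      hap <- ifelse(v == 1L, m1, m2)
      mres <- mutate_haplotype(hap, config, pools, prov_bclass)
      if (sexes[ci] == "male") {
        add(x_individual(fid, cid, father_id = if (need_father) "DAD" else NA,
                         mother_id = "MOM", sex = "male",
                         alleles = mres$hap))
      } else {
        add(x_individual(fid, cid, father_id = if (need_father) "DAD" else NA,
                         mother_id = "MOM", sex = "female",
                         alleles = rbind(mres$hap, father_hap)))
      }
      fam_truth$children[[cid]] <- list(
        id = cid, sex = sexes[ci], v = v, mutated = mres$mutated,
        maternal_hap = mres$hap)
    }
    truth[[fid]] <- fam_truth
  }

  if (config$missing_rate > 0) {
    for (i in seq_along(individuals)) {
      drop <- stats::runif(n) < config$missing_rate
      if (!any(drop)) next
      if (individuals[[i]]$sex == "male") {
        individuals[[i]]$alleles[drop] <- NA_real_
      } else {
        individuals[[i]]$alleles[, drop] <- NA_real_
      }
    }
  }

  # canonicalize POLY codes to first-appearance order in the emitted file so
  # that parse_ped(write_ped(.)) is the identity on codes
  remap <- canonical_poly_remap(individuals, config, prov_maps)
  individuals <- remap$individuals
  panel <- marker_panel(paste0("M", seq_len(n)), config$marker_types,
                        remap$allele_maps)
  for (fid in names(truth)) {
    truth[[fid]]$m1 <- remap$recode(truth[[fid]]$m1)
    truth[[fid]]$m2 <- remap$recode(truth[[fid]]$m2)
    for (cid in names(truth[[fid]]$children)) {
      truth[[fid]]$children[[cid]]$maternal_hap <-
        remap$recode(truth[[fid]]$children[[cid]]$maternal_hap)
    }
  }
  names(individuals) <- vapply(individuals, ind_key, "")
  structure(list(individuals = individuals, panel = panel, truth = truth,
                 config = config),
            class = "xrecomb_sim")
}

# Reassign POLY codes by order of first appearance scanning individuals in
# output order (row-major over the two allele columns, as a PED reader sees
# them). Returns remapped individuals, final allele maps, and a recoder.
canonical_poly_remap <- function(individuals, config, prov_maps) {
  n <- config$n_markers
  poly <- which(config$marker_types == "POLY")
  code_map <- vector("list", n)  # old code index -> new code
  allele_maps <- vector("list", n)
  for (j in poly) {
    seen <- numeric(0)
    for (ind in individuals) {
      al <- if (ind$sex == "male") {
        rep(ind$alleles[j], 2L)
      } else {
        # mirror write_ped's emission order for POLY pairs
        sort(ind$alleles[, j], decreasing = TRUE, na.last = TRUE)
      }
      for (a in al) {
        if (!is.na(a) && !(a %in% seen)) seen <- c(seen, a)
      }
    }
    # unobserved pool alleles keep trailing codes for map completeness
    seen <- c(seen, setdiff(-seq_along(config$poly_alleles), seen))
    newcode <- stats::setNames(-seq_along(seen), as.character(seen))
    code_map[[j]] <- newcode
    strings <- config$poly_alleles[-as.integer(seen)]
    allele_maps[[j]] <- stats::setNames(as.numeric(newcode), strings)
  }
  recode <- function(hap) {
    for (j in poly) {
      if (!is.na(hap[j])) {
        hap[j] <- unname(code_map[[j]][as.character(hap[j])])
      }
    }
    hap
  }
  for (i in seq_along(individuals)) {
    ind <- individuals[[i]]
    if (ind$sex == "male") {
      ind$alleles <- recode(ind$alleles)
    } else {
      ind$alleles[1L, ] <- recode(ind$alleles[1L, ])
      ind$alleles[2L, ] <- recode(ind$alleles[2L, ])
      ind$alleles <- apply(ind$alleles, 2, function(p) {
        if (anyNA(p)) c(NA_real_, NA_real_) else sort(p)
      })
      if (is.null(dim(ind$alleles))) ind$alleles <- matrix(ind$alleles, 2L)
    }
    individuals[[i]] <- ind
  }
  list(individuals = individuals, allele_maps = allele_maps, recode = recode)
}

#' Write the simulation truth record as a tab-separated sidecar
#'
#' One row per mother haplotype and per child, with comma-joined vectors for
#' haplotypes, inheritance vectors and mutation flags.
#'
#' @param sim an `xrecomb_sim` object from [simulate_pedigrees()].
#' @param path output path.
#' @return `invisible(path)`.
#' @export
write_truth <- function(sim, path) {
  rows <- list()
  for (fam in sim$truth) {
    rows[[length(rows) + 1L]] <- data.frame(
      family_id = fam$family_id, kind = fam$kind, role = "mother",
      individual = "MOM",
      hap = paste(fam$m1, collapse = ","),
      hap2 = paste(fam$m2, collapse = ","),
      inheritance = NA, mutated = NA)
    for (ch in fam$children) {
      rows[[length(rows) + 1L]] <- data.frame(
        family_id = fam$family_id, kind = fam$kind, role = "child",
        individual = ch$id,
        hap = paste(ch$maternal_hap, collapse = ","),
        hap2 = NA,
        inheritance = paste(ch$v, collapse = ","),
        mutated = paste(as.integer(ch$mutated), collapse = ","))
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
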