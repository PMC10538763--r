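#' Phased and unphased mothers
#'
#' `phased_mother()` holds a mother's two ordered haplotypes (as recovered
#' from her own father, or as simulation ground truth). `unphased_mother()`
#' holds only the unordered genotype; the set of phasings compatible with it
#' has size 2^(h-1), where h is the number of heterozygous markers (phase is
#' anchored at the first heterozygous marker; a fully homozygous genotype has
#' a single phasing).
#'
#' @param hap1,hap2 numeric allele-code vectors of equal length.
#' @param source provenance tag for the phase.
#' @return An object of class `phased_mother` / `unphased_mother`.
#' @export
phased_mother <- function(hap1, hap2, source = "grandfather-phased") {
  if (length(hap1) != length(hap2)) stop("haplotypes differ in length")
  structure(list(hap1 = as.numeric(hap1), hap2 = as.numeric(hap2),
                 source = source),
            class = "phased_mother")
}

#' @rdname phased_mother
#' @param genotype 2 x n numeric matrix of unordered allele pairs.
#' @export
unphased_mother <- function(genotype) {
  if (is.null(dim(genotype)) || nrow(genotype) != 2L) {
    stop("genotype must be a 2 x n matrix")
  }
  g <- apply(genotype, 2, function(p) if (anyNA(p)) c(NA_real_, NA_real_) else sort(p))
  if (is.null(dim(g))) g <- matrix(g, nrow = 2L)
  het <- !is.na(g[1L, ]) & g[1L, ] != g[2L, ]
  structure(list(genotype = g, het_mask = het), class = "unphased_mother")
}

#' Informative family unit
#'
#' A type I family is a phased mother with at least one child whose maternal
#' haplotype is observable (sons directly; daughters via paternal
#' subtraction). A type II family is an unphased mother with at least two
#' such children; its likelihood sums over all compatible maternal phasings.
#'
#' @param kind `"typeI"` or `"typeII"`.
#' @param mother a [phased_mother()] (type I) or [unphased_mother()] (type II).
#' @param children list of numeric maternal-haplotype vectors, one per child.
#' @param panel the [marker_panel()] the haplotypes are encoded against.
#' @param provenance optional list of source-individual identifiers.
#' @return An object of class `informative_family`.
#' @export
informative_family <- function(kind, mother, children, panel,
                               provenance = NULL) {
  kind <- match.arg(kind, c("typeI", "typeII"))
  if (kind == "typeI") {
    if (!inherits(mother, "phased_mother")) stop("type I needs a phased mother")
    if (length(children) < 1L) stop("type I family needs at least 1 child")
  } else {
    if (!inherits(mother, "unphased_mother")) {
      stop("type II needs an unphased mother")
    }
    if (length(children) < 2L) stop("type II family needs at least 2 children")
  }
  n <- panel$n_markers
  for (h in children) {
    if (length(h) != n) stop("child haplotype length != panel size")
  }
  structure(list(kind = kind, mother = mother,
                 children = lapply(children, as.numeric),
                 panel = panel, provenance = provenance),
            class = "informative_family")
}

#' @export
print.informative_family <- function(x, ...) {
  cat("Informative family (", x$kind, "), ", length(x$children),
      " child(ren), ", x$panel$n_markers, " markers\n", sep = "")
  invisible(x)
}

#' Build relatedness graphs from a set of individuals
#'
#' Constructs a directed parent-to-child graph over all individuals and
#' returns one graph per connected component. Parent references must be
#' sex-consistent (a `father_id` must resolve to a male, a `mother_id` to a
#' female); a parent ID that resolves to no individual in the same family is
#' treated as absent with a warning. Cycles are a data error.
#'
#' @param individuals list of [x_individual()].
#' @return A list of `igraph` graphs; each carries its individuals in the
#'   graph attribute `individuals` (named by `family::id`).
#' @export
build_family_graphs <- function(individuals) {
  if (length(individuals) == 0L) return(list())
  names(individuals) <- vapply(individuals, ind_key, "")
  keys <- names(individuals)
  edges <- character(0)
  for (ind in individuals) {
    for (pfield in c("father_id", "mother_id")) {
      pid <- ind[[pfield]]
      if (is.na(pid)) next
      pkey <- paste(ind$family_id, pid, sep = "::")
      parent <- individuals[[pkey]]
      if (is.null(parent)) {
        warning("parent '", pid, "' of individual '", ind$id,
                "' (family ", ind$family_id, ") not in dataset; ",
                "treated as absent")
        next
      }
      want <- if (pfield == "father_id") "male" else "female"
      if (parent$sex != want) {
        stop("data error: ", pfield, " '", pid, "' of individual '",
             ind$id, "' (family ", ind$family_id, ") is not ", want)
      }
      edges <- c(edges, pkey, ind_key(ind))
    }
  }
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(keys)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  if (!igraph::is_dag(g)) stop("data error: parent-child cycle in pedigree")
  comp <- igraph::components(g, mode = "weak")
  lapply(seq_len(comp$no), function(ci) {
    vk <- keys[comp$membership == ci]
    sg <- igraph::induced_subgraph(g, vk)
    sg <- igraph::set_graph_attr(sg, "individuals", individuals[vk])
    sg
  })
}

#' Phase a daughter by paternal subtraction
#'
#' On the X chromosome a father transmits his whole haplotype to every
#' daughter, so her maternal allele at each marker is her genotype pair minus
#' the paternal allele. Markers where either side is missing stay missing. A
#' marker where the father's allele is absent from the daughter's pair is a
#' phasing conflict (e.g. a paternal-line mutation, which the likelihood model
#' does not cover): the marker is set missing and its index recorded.
#'
#' @param daughter a female [x_individual()].
#' @param father a male [x_individual()] (the daughter's father).
#' @return The daughter's maternal haplotype (numeric vector) with an integer
#'   attribute `conflicts` listing conflicting marker indices (empty if none).
#' @export
phase_daughter <- function(daughter, father) {
  if (daughter$sex != "female") stop("daughter must be female")
  if (father$sex != "male") stop("father must be male")
  n <- ind_n_markers(daughter)
  if (ind_n_markers(father) != n) stop("marker count mismatch")
  hap <- rep(NA_real_, n)
  conflicts <- integer(0)
  for (j in seq_len(n)) {
    d1 <- daughter$alleles[1L, j]; d2 <- daughter$alleles[2L, j]
    f <- father$alleles[j]
    if (is.na(f) || is.na(d1)) next
    if (f == d1) hap[j] <- d2
    else if (f == d2) hap[j] <- d1
    else conflicts <- c(conflicts, j)
  }
  attr(hap, "conflicts") <- conflicts
  hap
}

#' Phase a mother through her own father (the maternal grandfather)
#'
#' The grandfather's haplotype is one of the mother's two haplotypes, so
#' subtraction recovers both: `hap1` takes the grandfather's allele wherever
#' it appears in the mother's pair, `hap2` the remainder. Any marker where
#' the grandfather's allele is absent from the mother's pair — or where the
#' grandfather is untyped but the mother is heterozygous — voids the phase
#' (the mother can still found a type II family).
#'
#' @param mother a female [x_individual()].
#' @param grandfather a male [x_individual()] (the mother's father).
#' @return A [phased_mother()] on success, otherwise `NULL` (with a warning
#'   naming the offending markers).
#' @export
phase_mother_by_grandfather <- function(mother, grandfather) {
  if (mother$sex != "female") stop("mother must be female")
  if (grandfather$sex != "male") stop("grandfather must be male")
  n <- ind_n_markers(mother)
  if (ind_n_markers(grandfather) != n) stop("marker count mismatch")
  hap1 <- rep(NA_real_, n)
  hap2 <- rep(NA_real_, n)
  bad <- integer(0)
  for (j in seq_len(n)) {
    m1 <- mother$alleles[1L, j]; m2 <- mother$alleles[2L, j]
    g <- grandfather$alleles[j]
    if (is.na(m1)) next
    if (is.na(g)) {
      if (m1 == m2) { hap1[j] <- m1; hap2[j] <- m2 } else bad <- c(bad, j)
      next
    }
    if (g == m1) { hap1[j] <- m1; hap2[j] <- m2 }
    else if (g == m2) { hap1[j] <- m2; hap2[j] <- m1 }
    else bad <- c(bad, j)
  }
  if (length(bad)) {
    warning("phasing conflict between mother '", mother$id,
            "' and grandfather '", grandfather$id, "' at marker index ",
            paste(bad, collapse = ","), "; mother left unphased")
    return(NULL)
  }
  phased_mother(hap1, hap2)
}

#' Extract informative families from relatedness graphs
#'
#' Walks every genotyped mother in each graph, collects the children whose
#' maternal haplotype is observable (sons directly; daughters by
#' [phase_daughter()] when their father is genotyped) and classifies the
#' unit: type I when the mother's own father is genotyped and phasing
#' succeeds (>= 1 child needed), otherwise type II (>= 2 children needed).
#' A single pedigree can yield several families, one per qualifying mother;
#' a female phased through her father can in turn serve as a phased mother
#' for her own children. Mothers with any missing genotype marker are skipped
#' (a logged message), as summing over phasings with unknown alleles is
#' unsupported. Extraction is deterministic and independent of the input
#' ordering: families are sorted by family and mother ID, children by ID.
#'
#' @param graphs list of graphs from [build_family_graphs()].
#' @param panel the [marker_panel()].
#' @return A list of [informative_family()] objects.
#' @export
extract_families <- function(graphs, panel) {
  fams <- list()
  for (g in graphs) {
    inds <- igraph::graph_attr(g, "individuals")
    if (is.null(inds)) stop("graph lacks its individuals attribute")
    for (key in sort(names(inds))) {
      mother <- inds[[key]]
      if (mother$sex != "female") next
      kids <- Filter(function(x) identical(x$mother_id, mother$id) &&
                       identical(x$family_id, mother$family_id), inds)
      if (length(kids) == 0L) next
      if (anyNA(mother$alleles)) {
        message("skipping mother '", mother$id, "' (family ",
                mother$family_id, "): missing genotype markers")
        next
      }
      kids <- kids[order(vapply(kids, function(x) x$id, ""))]
      child_haps <- list()
      child_ids <- character(0)
      for (kid in kids) {
        if (kid$sex == "male") {
          child_haps[[length(child_haps) + 1L]] <- as.numeric(kid$alleles)
          child_ids <- c(child_ids, kid$id)
        } else {
          if (is.na(kid$father_id)) {
            message("skipping daughter '", kid$id, "' (family ",
                    kid$family_id, "): father not genotyped")
            next
          }
          father <- inds[[paste(kid$family_id, kid$father_id, sep = "::")]]
          if (is.null(father)) {
            message("skipping daughter '", kid$id, "' (family ",
                    kid$family_id, "): father not genotyped")
            next
          }
          hap <- phase_daughter(kid, father)
          if (length(attr(hap, "conflicts"))) {
            warning("phasing conflict between daughter '", kid$id,
                    "' and father '", father$id, "' (family ",
                    kid$family_id, "); daughter excluded")
            next
          }
          attr(hap, "conflicts") <- NULL
          child_haps[[length(child_haps) + 1L]] <- hap
          child_ids <- c(child_ids, kid$id)
        }
      }
      gf_id <- mother$father_id
      pm <- NULL
      if (!is.na(gf_id)) {
        gf <- inds[[paste(mother$family_id, gf_id, sep = "::")]]
        if (!is.null(gf) && gf$sex == "male") {
          pm <- phase_mother_by_grandfather(mother, gf)
        }
      }
      prov <- list(family_id = mother$family_id, mother_id = mother$id,
                   grandfather_id = if (is.null(pm)) NA_character_ else gf_id,
                   child_ids = child_ids)
      if (!is.null(pm) && length(child_haps) >= 1L) {
        fams[[length(fams) + 1L]] <- informative_family(
          "typeI", pm, child_haps, panel, prov)
      } else if (length(child_haps) >= 2L) {
        fams[[length(fams) + 1L]] <- informative_family(
          "typeII", unphased_mother(mother$alleles), child_haps, panel, prov)
      } else {
        message("mother '", mother$id, "' (family ", mother$family_id,
                ") not informative: unphased with ", length(child_haps),
                " observable child(ren)")
      }
    }
  }
  ord <- order(vapply(fams, function(f) paste(f$provenance$family_id,
                                              f$provenance$mother_id), ""))
  fams[ord]
}
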