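#' Pedigree individual
#'
#' Construct an individual record as parsed from (or destined for) a PLINK
#' PED file. Males are hemizygous on X: they carry a single allele per marker
#' (their maternal haplotype read directly). Females carry an unordered allele
#' pair per marker, stored canonically sorted so that phase information is
#' never implied by storage order.
#'
#' @param family_id,id character identifiers; `id` must be unique within the
#'   family.
#' @param father_id,mother_id parent identifiers or `NA` when unknown.
#' @param sex `"male"` or `"female"`.
#' @param alleles for a male, a numeric vector of n allele codes; for a
#'   female, a 2 x n numeric matrix (rows are the two alleles at each marker,
#'   order irrelevant). `NA` marks a missing marker.
#' @param phenotype phenotype column carried through verbatim (default "0").
#' @return An object of class `x_individual`.
#' @export
x_individual <- function(family_id, id, father_id = NA, mother_id = NA,
                         sex, alleles, phenotype = "0") {
  sex <- match.arg(sex, c("male", "female"))
  if (sex == "male") {
    if (!is.null(dim(alleles))) stop("male individual takes an allele vector")
    alleles <- as.numeric(alleles)
  } else {
    if (is.null(dim(alleles)) || nrow(alleles) != 2L) {
      stop("female individual takes a 2 x n allele matrix")
    }
    alleles <- apply(alleles, 2, function(p) {
      if (anyNA(p)) c(NA_real_, NA_real_) else sort(p)
    })
    if (is.null(dim(alleles))) alleles <- matrix(alleles, nrow = 2L)
    dimnames(alleles) <- NULL
  }
  structure(
    list(family_id = as.character(family_id), id = as.character(id),
         father_id = if (is.na(father_id)) NA_character_ else as.character(father_id),
         mother_id = if (is.na(mother_id)) NA_character_ else as.character(mother_id),
         sex = sex, alleles = alleles, phenotype = as.character(phenotype)),
    class = "x_individual"
  )
}

ind_key <- function(ind) paste(ind$family_id, ind$id, sep = "::")

ind_n_markers <- function(ind) {
  if (ind$sex == "male") length(ind$alleles) else ncol(ind$alleles)
}

# regex for an STR allele: integer repeat count with at most one decimal digit
.str_allele_re <- "^[0-9]+(\\.[0-9])?$"

#' Parse a PLINK PED file
#'
#' Reads whitespace-delimited PED rows (family ID, individual ID, father ID,
#' mother ID, sex, phenotype, then two allele columns per marker; `0` denotes
#' a missing allele or parent). Marker types are inferred per marker: if every
#' observed allele is numeric (at most one decimal digit) the marker is STR,
#' otherwise POLY; non-STR alleles are encoded as negative integers in
#' decreasing order of first appearance in the file. A marker-info file may
#' override names and types.
#'
#' Males must be written with a single allele duplicated (`10 10`); two
#' different alleles at a marker for a male is a data error. Female genotypes
#' with only one missing allele are treated as fully missing at that marker
#' (with a warning).
#'
#' @param path path to the PED file.
#' @param marker_info optional path to a tab-separated file with header
#'   columns `name` and `type` (`STR` or `POLY`), one row per marker in PED
#'   column order.
#' @return A list with elements `panel` (a [marker_panel()]) and
#'   `individuals` (list of [x_individual()], named by `family::id`).
#' @export
parse_ped <- function(path, marker_info = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("PED file '", path, "' is empty")
  toks <- strsplit(trimws(lines), "[ \t]+")
  nc <- lengths(toks)
  if (any(nc != nc[1])) {
    bad <- which(nc != nc[1])[1]
    stop("PED parse error: line ", bad, " has ", nc[bad],
         " fields; expected ", nc[1])
  }
  nc <- nc[1]
  if (nc < 8L || (nc - 6L) %% 2L != 0L) {
    stop("PED parse error: expected 6 leading columns plus an even number ",
         "of genotype columns, got ", nc, " fields")
  }
  n <- (nc - 6L) %/% 2L
  tok <- do.call(rbind, toks)

  # marker names / types
  mnames <- paste0("M", seq_len(n))
  types <- NULL
  if (!is.null(marker_info)) {
    mi <- utils::read.delim(marker_info, header = TRUE, sep = "\t",
                            colClasses = "character")
    if (!all(c("name", "type") %in% names(mi))) {
      stop("marker-info file needs columns 'name' and 'type'")
    }
    if (nrow(mi) != n) {
      stop("marker-info file has ", nrow(mi), " rows but PED has ",
           n, " markers")
    }
    mnames <- mi$name
    types <- toupper(mi$type)
    if (!all(types %in% c("STR", "POLY"))) {
      stop("marker-info types must be STR or POLY")
    }
  }

  acols <- lapply(seq_len(n), function(j) cbind(tok[, 5L + 2L * j],
                                                tok[, 6L + 2L * j]))
  if (is.null(types)) {
    types <- vapply(acols, function(ac) {
      obs <- ac[ac != "0"]
      if (length(obs) && all(grepl(.str_allele_re, obs))) "STR" else "POLY"
    }, "")
  }

  # POLY allele maps: codes by decreasing negative integers in order of first
  # appearance (row-major: row by row, left allele then right allele)
  allele_maps <- vector("list", n)
  for (j in seq_len(n)) {
    if (types[j] == "POLY") {
      obs <- as.vector(t(acols[[j]]))  # row-major over (left, right)
      obs <- obs[obs != "0"]
      firsts <- unique(obs)
      if (length(firsts) == 0L) {
        stop("POLY marker '", mnames[j], "' has no observed alleles")
      }
      allele_maps[[j]] <- stats::setNames(-seq_along(firsts), firsts)
    } else {
      obs <- acols[[j]][acols[[j]] != "0"]
      bad <- obs[!grepl(.str_allele_re, obs)]
      if (length(bad)) {
        stop("marker '", mnames[j], "' declared STR but allele '", bad[1],
             "' is not a repeat count with at most one decimal digit")
      }
    }
  }
  panel <- marker_panel(mnames, types, allele_maps)

  code1 <- function(s, j) {
    if (s == "0") return(NA_real_)
    if (types[j] == "STR") as.numeric(s) else unname(allele_maps[[j]][s])
  }

  individuals <- list()
  for (r in seq_len(nrow(tok))) {
    fid <- tok[r, 1]; iid <- tok[r, 2]
    pat <- tok[r, 3]; mat <- tok[r, 4]
    sx <- tok[r, 5]; phe <- tok[r, 6]
    sex <- switch(sx, "1" = "male", "2" = "female",
                  stop("data error: unknown sex code '", sx,
                       "' for individual ", iid, " (line ", r, ")"))
    key <- paste(fid, iid, sep = "::")
    if (!is.null(individuals[[key]])) {
      stop("data error: duplicated individual ID '", iid,
           "' within family '", fid, "'")
    }
    if (sex == "male") {
      al <- rep(NA_real_, n)
      for (j in seq_len(n)) {
        a <- code1(tok[r, 5L + 2L * j], j)
        b <- code1(tok[r, 6L + 2L * j], j)
        if (is.na(a) && is.na(b)) next
        if (is.na(a) || is.na(b) || a != b) {
          stop("data error: male ", iid, " has two different alleles at ",
               "marker ", mnames[j])
        }
        al[j] <- a
      }
    } else {
      al <- matrix(NA_real_, 2L, n)
      for (j in seq_len(n)) {
        a <- code1(tok[r, 5L + 2L * j], j)
        b <- code1(tok[r, 6L + 2L * j], j)
        if (xor(is.na(a), is.na(b))) {
          warning("half-missing genotype for ", iid, " at marker ",
                  mnames[j], "; treated as missing")
          a <- b <- NA_real_
        }
        al[, j] <- c(a, b)
      }
    }
    ind <- x_individual(fid, iid,
                        father_id = if (pat == "0") NA else pat,
                        mother_id = if (mat == "0") NA else mat,
                        sex = sex, alleles = al, phenotype = phe)
    individuals[[key]] <- ind
  }
  list(panel = panel, individuals = individuals)
}

#' Write individuals to a PLINK PED file
#'
#' Inverse of [parse_ped()]: males are written with their single allele
#' duplicated, missing markers as `0 0`, absent parents as `0`, and non-STR
#' codes decoded back to their original allele strings.
#'
#' @param individuals list of [x_individual()].
#' @param panel the shared [marker_panel()].
#' @param path output file path.
#' @return `invisible(path)`.
#' @export
write_ped <- function(individuals, panel, path) {
  n <- panel$n_markers
  rows <- vapply(individuals, function(ind) {
    if (ind_n_markers(ind) != n) {
      stop("individual ", ind$id, " has ", ind_n_markers(ind),
           " markers; panel has ", n)
    }
    gcols <- character(2L * n)
    for (j in seq_len(n)) {
      if (ind$sex == "male") {
        s <- decode_allele(ind$alleles[j], j, panel)
        gcols[c(2L * j - 1L, 2L * j)] <- c(s, s)
      } else {
        pair <- ind$alleles[, j]
        # POLY pairs are emitted in descending code order (-1 before -2),
        # which is first-appearance order, so re-parsing the file derives
        # the same allele encoding (write/parse is idempotent)
        if (panel$types[j] == "POLY" && !anyNA(pair)) {
          pair <- sort(pair, decreasing = TRUE)
        }
        gcols[2L * j - 1L] <- decode_allele(pair[1L], j, panel)
        gcols[2L * j] <- decode_allele(pair[2L], j, panel)
      }
    }
    paste(c(ind$family_id, ind$id,
            ifelse(is.na(ind$father_id), "0", ind$father_id),
            ifelse(is.na(ind$mother_id), "0", ind$mother_id),
            if (ind$sex == "male") "1" else "2",
            ind$phenotype, gcols), collapse = " ")
  }, "")
  writeLines(rows, path)
  invisible(path)
}

#' Write a marker-info file for a panel
#'
#' Emits the two-column tab-separated `name`/`type` table consumed by the
#' `marker_info` argument of [parse_ped()].
#'
#' @param panel a [marker_panel()].
#' @param path output path.
#' @return `invisible(path)`.
#' @export
write_marker_info <- function(panel, path) {
  utils::write.table(
    data.frame(name = panel$names, type = panel$types),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
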