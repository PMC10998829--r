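#' Read a GenePop genotype file
#'
#' Parses the GenePop dialect used as the package's on-disk interchange
#' format: a title line, locus names (one per line or comma-separated on
#' one line), then populations separated by \code{pop} lines, with one
#' individual per line as \code{name , 100104 000000 ...}.  Both 2- and
#' 3-digit allele codes are understood; the all-zero code maps to a missing
#' genotype.  Populations receive positional labels \code{pop1},
#' \code{pop2}, ... (the format itself carries no population names).
#'
#' @param path file path.
#' @return A \linkS4class{GenotypeTable}.
#' @export
readGenepop <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[!grepl("^\\s*$", ln)]
  if (length(ln) < 3) stop("not a GenePop file: too few lines")
  body <- ln[-1]
  popIdx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!length(popIdx)) stop("not a GenePop file: no 'pop' line")
  locLines <- body[seq_len(popIdx[1] - 1)]
  loci <- unlist(strsplit(locLines, ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("no locus names before first 'pop'")

  indLines <- list(); popOf <- integer(0)
  bounds <- c(popIdx, length(body) + 1L)
  for (p in seq_along(popIdx)) {
    seg <- body[seq(bounds[p] + 1L, bounds[p + 1L] - 1L)]
    seg <- seg[!grepl("^\\s*pop\\s*$", seg, ignore.case = TRUE)]
    indLines <- c(indLines, as.list(seg))
    popOf <- c(popOf, rep(p, length(seg)))
  }
  n <- length(indLines)
  a <- b <- matrix(NA_integer_, n, length(loci),
                   dimnames = list(NULL, loci))
  nm <- character(n)
  width <- NA_integer_
  for (i in seq_len(n)) {
    parts <- strsplit(indLines[[i]], ",")[[1]]
    if (length(parts) < 2)
      stop("malformed individual line (no comma): ", indLines[[i]])
    nm[i] <- trimws(parts[1])
    geno <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    geno <- geno[nzchar(geno)]
    if (length(geno) != length(loci))
      stop(sprintf("ragged genotype row for '%s': %d fields, %d loci",
                   nm[i], length(geno), length(loci)))
    w <- unique(nchar(geno)) / 2
    if (length(unique(nchar(geno))) > 1 || !(w[1] %in% c(2, 3)))
      stop("unknown allele-code width in row for '", nm[i], "'")
    if (is.na(width)) width <- as.integer(w[1])
    else if (width != w[1])
      stop("inconsistent allele-code width at row for '", nm[i], "'")
    a1 <- as.integer(substr(geno, 1, width))
    a2 <- as.integer(substr(geno, width + 1, 2 * width))
    a1[a1 == 0L] <- NA_integer_; a2[a2 == 0L] <- NA_integer_
    miss <- is.na(a1) | is.na(a2)
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    a[i, ] <- a1; b[i, ] <- a2
  }
  if (anyDuplicated(nm)) nm <- make.unique(nm)
  rownames(a) <- rownames(b) <- nm
  genotypeTable(a, b, pop = paste0("pop", popOf))
}

#' Write a GenotypeTable as a 3-digit GenePop file
#'
#' Individuals are emitted in input order, grouped into populations by
#' their pop label (individuals with an \code{NA} label form one
#' population).  Missing genotypes are written as \code{000000}.
#'
#' @param table a \linkS4class{GenotypeTable}.
#' @param path output file path.
#' @param title title line content.
#' @return Invisibly, the path.
#' @export
writeGenepop <- function(table, path, title = "msatpva genotypes") {
  a <- table@alleleA; b <- table@alleleB
  mx <- suppressWarnings(max(c(a, b), na.rm = TRUE))
  if (is.finite(mx) && mx >= 1000)
    stop("allele size >= 1000 cannot be encoded with 3-digit codes")
  pop <- table@pop
  pop[is.na(pop)] <- "pop1"
  out <- c(title, colnames(a))
  if (nrow(a) == 0) out <- c(out, "pop")
  for (pl in unique(pop)) {
    out <- c(out, "pop")
    for (i in which(pop == pl)) {
      g <- sprintf("%03d%03d",
                   ifelse(is.na(a[i, ]), 0L, a[i, ]),
                   ifelse(is.na(b[i, ]), 0L, b[i, ]))
      out <- c(out, paste0(rownames(a)[i], " ,  ", paste(g, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read replicate PCR calls from TSV
#'
#' The replicate-call file is a plain TSV with columns \code{sample},
#' \code{locus}, \code{replicate}, \code{allele1}, \code{allele2}; empty
#' allele fields mark a failed amplification (not a homozygote).
#'
#' @param path file path.
#' @return A \linkS4class{ReplicateCalls}.
#' @export
readReplicates <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(sample = "character",
                                        locus = "character"))
  need <- c("sample", "locus", "replicate", "allele1", "allele2")
  if (!all(need %in% names(d)))
    stop("replicate file must have columns: ", paste(need, collapse = ", "))
  d$allele1 <- suppressWarnings(as.integer(d$allele1))
  d$allele2 <- suppressWarnings(as.integer(d$allele2))
  miss <- is.na(d$allele1) | is.na(d$allele2)
  d$allele1[miss] <- NA_integer_; d$allele2[miss] <- NA_integer_
  sw <- !miss & d$allele1 > d$allele2
  if (any(sw)) {
    tmp <- d$allele1[sw]; d$allele1[sw] <- d$allele2[sw]; d$allele2[sw] <- tmp
  }
  new("ReplicateCalls", calls = d[need])
}

#' Write replicate PCR calls to TSV
#'
#' @param calls a \linkS4class{ReplicateCalls}.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeReplicates <- function(calls, path) {
  utils::write.table(calls@calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a tree in Newick format
#'
#' Thin wrapper around \code{\link[ape]{write.tree}} that flags negative
#' branch lengths (neighbor joining can produce them) instead of failing.
#'
#' @param tree an \code{ape} \code{phylo} object.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeNewick <- function(tree, path) {
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    warning("tree has negative branch lengths; written as-is")
  ape::write.tree(tree, file = path)
  invisible(path)
}
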