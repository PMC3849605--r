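#' Read protein chains from a FASTA file
#'
#' One [AnnotatedChain-class] per record (no profile attached). The chain id
#' is the first whitespace-delimited word of the header. Letters outside the
#' 20-letter alphabet are mapped to `X`.
#'
#' @param path FASTA file path.
#' @return list of [AnnotatedChain-class] objects, named by id.
#' @export
readFastaChains <- function(path) {
  seqs <- tryCatch(Biostrings::readAAStringSet(path),
                   error = function(e) stop("could not parse FASTA input: ", conditionMessage(e)))
  if (length(seqs) == 0L) stop("empty FASTA input: no records found")
  if (any(Biostrings::width(seqs) == 0L)) stop("FASTA format error: record with empty sequence")
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  chains <- lapply(seq_along(seqs), function(i)
    annotatedChain(ids[i], as.character(seqs[[i]])))
  names(chains) <- ids
  chains
}

#' Write chains to a FASTA file
#' @param chains list of [AnnotatedChain-class].
#' @param path output path.
#' @export
writeFastaChains <- function(chains, path) {
  set <- Biostrings::AAStringSet(vapply(chains, chainSeq, ""))
  names(set) <- vapply(chains, chainId, "")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Parse a PSI-BLAST ASCII PSSM into a profile matrix
#'
#' Reads the checkpoint-style ASCII matrix written by `psiblast
#' -out_ascii_pssm`. Frequencies are taken from the 20 percentage columns
#' (the "weighted observed percentages"), divided by 100; the 20 log-odds
#' columns are ignored. An all-zero percentage row is replaced by the
#' one-hot distribution of the query residue at that position (uniform for
#' `X`), and every row is renormalised to sum to 1.
#'
#' @param path PSSM file path (or a character vector of lines).
#' @return numeric matrix (positions x 20), columns in [AA_ALPHABET20]
#'   order; attribute `query` holds the query sequence read from the file.
#' @export
parsePSSM <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  ## header line carries the 40 amino-acid column labels
  headIdx <- grep("^\\s*[A-Z](\\s+[A-Z]){19,}\\s*$", lines)
  if (!length(headIdx)) stop("PSSM format error: no amino-acid header line found")
  headerLetters <- strsplit(trimws(lines[headIdx[1]]), "\\s+")[[1]]
  if (length(headerLetters) == 40L) {
    percOrder <- headerLetters[21:40]
  } else if (length(headerLetters) == 20L) {
    percOrder <- headerLetters
  } else stop("PSSM format error: header must list 20 or 40 amino-acid columns")
  if (!setequal(percOrder, AA_ALPHABET20))
    stop("PSSM format error: header letters are not the 20 standard amino acids")

  dataLines <- grep("^\\s*\\d+\\s+[A-Za-z]\\s+-?\\d", lines, value = TRUE)
  if (!length(dataLines)) stop("PSSM format error: no per-residue rows found")
  rows <- strsplit(trimws(dataLines), "\\s+")
  query <- character(length(rows))
  freqs <- matrix(0, nrow = length(rows), ncol = 20,
                  dimnames = list(NULL, AA_ALPHABET20))
  for (r in seq_along(rows)) {
    f <- rows[[r]]
    ## pos, residue, 20 log-odds, 20 percentages, then optional info columns
    if (length(f) < 42L) stop("PSSM format error: row ", r, " has too few columns")
    res <- toupper(f[2])
    if (!res %in% c(AA_ALPHABET20, "X"))
      stop("PSSM format error: residue letter '", res, "' outside alphabet")
    query[r] <- res
    perc <- suppressWarnings(as.numeric(f[23:42]))
    if (any(is.na(perc))) stop("PSSM format error: non-numeric percentage in row ", r)
    freqs[r, percOrder] <- perc / 100
  }
  seq <- paste(query, collapse = "")
  out <- .normalizeProfile(freqs, seq)
  attr(out, "query") <- seq
  out
}

#' Write a profile matrix as a PSI-BLAST-style ASCII PSSM
#'
#' Emits the minimal ASCII layout [parsePSSM()] reads: a 40-letter header,
#' one row per residue with 20 (zeroed) log-odds columns and 20 percentage
#' columns. Percentages are rounded to integers, so a write/read round trip
#' reproduces frequencies to about 0.01.
#'
#' @param profile positions x 20 matrix.
#' @param sequence query sequence (length must match).
#' @param path output path.
#' @export
writePSSM <- function(profile, sequence, path) {
  letters20 <- strsplit(sequence, "")[[1]]
  stopifnot(nrow(profile) == length(letters20))
  profile <- .normalizeProfile(as.matrix(profile), sequence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed"), con)
  hdr <- paste(c(.BLAST_AA_ORDER, .BLAST_AA_ORDER), collapse = "   ")
  writeLines(paste0("            ", hdr), con)
  for (i in seq_len(nrow(profile))) {
    lo <- paste(rep.int("0", 20), collapse = "  ")
    ## largest-remainder rounding keeps each row summing to exactly 100
    x <- 100 * profile[i, .BLAST_AA_ORDER]
    base <- floor(x)
    short <- 100L - sum(base)
    if (short > 0) {
      bump <- order(x - base, decreasing = TRUE)[seq_len(short)]
      base[bump] <- base[bump] + 1
    }
    pc <- paste(sprintf("%3d", base), collapse = " ")
    writeLines(sprintf("%5d %s   %s   %s  0.00 0.00", i, letters20[i], lo, pc), con)
  }
  invisible(path)
}

#' Read disulfide bond annotations from a tabular bond list
#'
#' The dialect is one bond per line, tab-separated:
#' `chain<TAB>pos1<TAB>chain<TAB>pos2` with 1-based residue numbering (the
#' form easily produced from DSSP SS-bridge or PDB SSBOND records). Pairs
#' within one chain become bonds of that chain; a cysteine involved in an
#' inter-chain pair is excluded from its chain instead. Lines starting with
#' `#` are skipped.
#'
#' @param path file path (or character vector of lines).
#' @return named list, one entry per chain id, each a list with elements
#'   `bonds` (two-column integer matrix) and `excluded` (integer vector).
#' @export
readBondAnnotations <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  out <- list()
  addChain <- function(id) {
    if (is.null(out[[id]]))
      out[[id]] <<- list(bonds = matrix(integer(0), ncol = 2), excluded = integer(0))
  }
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1]]
    if (length(f) != 4L) stop("bond-list format error: expected 4 tab-separated fields in '", ln, "'")
    c1 <- f[1]; p1 <- suppressWarnings(as.integer(f[2]))
    c2 <- f[3]; p2 <- suppressWarnings(as.integer(f[4]))
    if (is.na(p1) || is.na(p2)) stop("bond-list format error: non-integer position in '", ln, "'")
    addChain(c1); addChain(c2)
    if (c1 == c2) {
      if (p1 == p2) stop("bond-list format error: self-bond at ", c1, ":", p1)
      out[[c1]]$bonds <- rbind(out[[c1]]$bonds, sort(c(p1, p2)))
    } else {
      out[[c1]]$excluded <- c(out[[c1]]$excluded, p1)
      out[[c2]]$excluded <- c(out[[c2]]$excluded, p2)
    }
  }
  for (id in names(out)) {
    b <- out[[id]]$bonds
    if (nrow(b)) {
      b <- unique(.canonicalBonds(b))
      if (anyDuplicated(as.vector(b)))
        stop("annotation conflict: a position of chain '", id,
             "' participates in more than one disulfide bond")
      if (any(as.vector(b) %in% out[[id]]$excluded))
        stop("annotation conflict: chain '", id,
             "' has a position both intra- and inter-chain bonded")
      out[[id]]$bonds <- b
    }
    out[[id]]$excluded <- sort(unique(out[[id]]$excluded))
  }
  out
}

#' Write disulfide patterns to the tabular bond list format
#'
#' @param patterns named list of [DisulfidePattern-class] (or bond matrices),
#'   names are chain ids; or a single pattern with `chain` given.
#' @param path output path.
#' @param chain chain id when `patterns` is a single pattern.
#' @export
writeBondList <- function(patterns, path, chain = NULL) {
  if (is(patterns, "DisulfidePattern") || is.matrix(patterns)) {
    stopifnot(!is.null(chain))
    patterns <- setNames(list(patterns), chain)
  }
  lines <- character(0)
  for (id in names(patterns)) {
    b <- bonds(if (is.matrix(patterns[[id]]))
      disulfidePattern(patterns[[id]]) else patterns[[id]])
    if (nrow(b))
      lines <- c(lines, sprintf("%s\t%d\t%s\t%d", id, b[, 1], id, b[, 2]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Apply the corpus chain-filtering rules
#'
#' Retains chains of length at least `minLength` with at least `minCys`
#' usable (non-excluded) cysteines. Very short chains are dropped because
#' profile generation is unreliable for them; chains with fewer than two
#' cysteines carry no disulfide information. Deterministic and
#' order-preserving, hence idempotent.
#'
#' @param chains list of [AnnotatedChain-class].
#' @param minLength minimum chain length (default 40).
#' @param minCys minimum number of usable cysteines (default 2).
#' @return filtered list.
#' @export
filterChains <- function(chains, minLength = 40L, minCys = 2L) {
  keep <- vapply(chains, function(ch)
    nchar(chainSeq(ch)) >= minLength && length(usableCys(ch)) >= minCys, TRUE)
  chains[keep]
}

#' Serialize / restore annotated chains as JSON
#'
#' @param chains list of [AnnotatedChain-class].
#' @param path JSON path.
#' @return `readChainsJSON` returns the list of chains.
#' @export
writeChainsJSON <- function(chains, path) {
  payload <- lapply(chains, function(ch) list(
    id = chainId(ch), sequence = chainSeq(ch),
    profile = if (hasProfile(ch)) unname(profileMatrix(ch)) else NULL,
    bonds = if (nrow(bonds(ch))) unname(bonds(ch)) else NULL,
    excluded = excludedCys(ch)))
  jsonlite::write_json(unname(payload), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeChainsJSON
#' @export
readChainsJSON <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  chains <- lapply(payload, function(rec) {
    profile <- if (!is.null(rec$profile))
      do.call(rbind, lapply(rec$profile, function(r) as.numeric(unlist(r))))
    bnds <- if (!is.null(rec$bonds))
      do.call(rbind, lapply(rec$bonds, function(r) as.integer(unlist(r))))
    annotatedChain(rec$id, rec$sequence, profile = profile, bonds = bnds,
                   excludedCys = as.integer(unlist(rec$excluded)))
  })
  names(chains) <- vapply(chains, chainId, "")
  chains
}
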