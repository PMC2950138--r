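#' Promoter sequence with upstream coordinates
#'
#' A promoter sequence carries a coordinate map in promoter convention:
#' position -1 is the base immediately upstream of the transcription start,
#' negative positions count further upstream, position +1 is the first
#' transcribed base, and there is no position 0.
#'
#' @param seq a single character string of bases in `A C G T N`.
#' @param start promoter coordinate of the first base (usually negative).
#' @param id sequence identifier.
#' @return An object of class `"promoter_sequence"`.
#' @export
promoter_sequence <- function(seq, start, id = "promoter") {
  seq <- toupper(as.character(seq))
  stopifnot(length(seq) == 1L, nchar(seq) >= 1L, start != 0)
  if (grepl("[^ACGTN]", seq)) stop("bases must be A, C, G, T or N")
  structure(list(id = id, seq = seq, start = as.integer(start)),
            class = "promoter_sequence")
}

#' @export
print.promoter_sequence <- function(x, ...) {
  cat(sprintf("promoter_sequence '%s': %d bp, coords %d..%d (no 0)\n",
              x$id, nchar(x$seq), x$start, pc_end(x)))
  invisible(x)
}

# 1-based string index of a promoter coordinate (no position 0)
pc_index <- function(ps, coord) {
  if (any(coord == 0)) stop("promoter coordinates have no position 0")
  idx <- coord - ps$start + 1L - as.integer(ps$start < 0 & coord > 0)
  if (any(idx < 1L | idx > nchar(ps$seq))) {
    stop("promoter coordinate outside sequence span")
  }
  idx
}

# last promoter coordinate covered by the sequence
pc_end <- function(ps) {
  len <- nchar(ps$seq)
  e <- ps$start + len - 1L
  if (ps$start < 0 && e >= 0) e <- e + 1L
  e
}

#' Read a promoter reference from FASTA
#'
#' Reads the first record of a FASTA file (via Biostrings) as a
#' [promoter_sequence()]. The promoter coordinate of the first base must be
#' supplied since FASTA carries no coordinate system.
#'
#' @param path FASTA file path.
#' @param start promoter coordinate of the first base.
#' @param reverse_complement set TRUE if the record is stored on the
#'   opposite strand from the probe (target-matching) sense.
#' @return A [promoter_sequence()].
#' @export
read_promoter_fasta <- function(path, start, reverse_complement = FALSE) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) < 1L) stop("empty FASTA")
  s <- ss[[1L]]
  if (reverse_complement) s <- Biostrings::reverseComplement(s)
  promoter_sequence(as.character(s), start, id = names(ss)[1L])
}

#' A variant on the promoter
#'
#' @param pos promoter coordinate of the first reference base affected.
#' @param ref,alt reference and alternate allele strings (alt may be `""`
#'   for a pure deletion).
#' @param label free-text name, e.g. `"-256A>TG"`.
#' @return list of class `"promoter_variant"`.
#' @export
variant <- function(pos, ref, alt, label = sprintf("%d%s>%s", pos, ref, alt)) {
  stopifnot(pos != 0, nchar(ref) >= 1L)
  structure(list(pos = as.integer(pos), ref = toupper(ref),
                 alt = toupper(alt), label = label),
            class = "promoter_variant")
}

#' Apply a variant to a promoter sequence
#'
#' Replaces the reference span by the alternate allele, yielding the
#' alternate allele sequence (net length change `nchar(alt) - nchar(ref)`;
#' +1 for an A-to-TG indel). Positions 3' of the variant shift accordingly,
#' so the returned object's coordinate map is exact only up to the variant
#' site; downstream use here is sequence matching, which is coordinate-free.
#'
#' @param ps a [promoter_sequence()].
#' @param v a [variant()]; `v$ref` must match the reference at `v$pos`.
#' @return A [promoter_sequence()] for the alternate allele.
#' @examples
#' ps <- promoter_sequence("GGTCAAAGAT", start = -260)
#' alt <- apply_variant(ps, variant(-256, "A", "TG", "-256A>TG"))
#' alt$seq  # "GGTCTGAAGAT": the A replaced by TG, net +1 base
#' @export
apply_variant <- function(ps, v) {
  stopifnot(inherits(ps, "promoter_sequence"), inherits(v, "promoter_variant"))
  i <- pc_index(ps, v$pos)
  found <- substr(ps$seq, i, i + nchar(v$ref) - 1L)
  if (found != v$ref) {
    stop(sprintf("reference mismatch at %d: expected '%s', found '%s'",
                 v$pos, v$ref, found))
  }
  new_seq <- paste0(substr(ps$seq, 1L, i - 1L), v$alt,
                    substr(ps$seq, i + nchar(v$ref), nchar(ps$seq)))
  out <- promoter_sequence(if (nchar(new_seq)) new_seq else "N",
                           ps$start, id = paste0(ps$id, "|", v$label))
  if (!nchar(new_seq)) out$seq <- ""
  attr(out, "variants") <- c(attr(ps, "variants"), list(v))
  out
}

#' Half-probe pair (MLPA ligation probe)
#'
#' Two adjacent half-probes hybridize on the target; only if the ligase
#' seals the nick between them is the probe amplified. Sequences are stored
#' in target-matching sense: the upstream half ends at `junction_pos` (a
#' promoter coordinate) and the downstream half starts immediately 3' of
#' it.
#'
#' @param probe_id identifier.
#' @param upstream,downstream half-probe target-matching sequences.
#' @param junction_pos promoter coordinate of the last upstream-matched
#'   base (the ligation site).
#' @param w junction window: bases on each side of the nick that must match
#'   the allele exactly for ligation (default 10).
#' @return list of class `"half_probe_pair"`.
#' @export
half_probe_pair <- function(probe_id, upstream, downstream, junction_pos,
                            w = 10L) {
  stopifnot(nchar(upstream) >= 1L, nchar(downstream) >= 1L,
            junction_pos != 0, w >= 1L)
  structure(list(probe_id = probe_id, upstream = toupper(upstream),
                 downstream = toupper(downstream),
                 junction_pos = as.integer(junction_pos), w = as.integer(w)),
            class = "half_probe_pair")
}

#' Read probe definitions from TSV
#'
#' Columns: `probe_id`, `upstream_seq`, `downstream_seq`, `junction_pos`,
#' optional `w`.
#'
#' @param path file path.
#' @param w default junction window when the file has no `w` column.
#' @return list of [half_probe_pair()] objects, named by probe id.
#' @export
read_probes_tsv <- function(path, w = 10L) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("probe_id", "upstream_seq", "downstream_seq", "junction_pos")
  stopifnot(all(need %in% names(df)))
  ww <- if ("w" %in% names(df)) df$w else rep(w, nrow(df))
  probes <- lapply(seq_len(nrow(df)), function(i) {
    half_probe_pair(df$probe_id[i], df$upstream_seq[i], df$downstream_seq[i],
                    df$junction_pos[i], ww[i])
  })
  names(probes) <- df$probe_id
  probes
}

#' Does a ligation probe yield signal on an allele?
#'
#' Ligation succeeds iff the `w` bases ending at the junction (from the
#' upstream half) and the `w` bases starting at the junction (downstream
#' half) match the allele exactly and contiguously — a perfectly apposed
#' nick. Any substitution, insertion or deletion inside that 2w-base window
#' abolishes the signal; variants outside it are tolerated (hybridization
#' survives mismatches away from the nick). Matching is binary, with no
#' thermodynamic model: nick-sealing failure is the modeled mechanism.
#'
#' @param probe a [half_probe_pair()].
#' @param allele a [promoter_sequence()] (reference or variant allele).
#' @return logical; on `FALSE` an attribute `reason` distinguishes
#'   `"junction_mismatch"` from `"no_hybridization"` (probe not found on
#'   the allele at all, within edit tolerance).
#' @export
ligation_success <- function(probe, allele) {
  stopifnot(inherits(probe, "half_probe_pair"),
            inherits(allele, "promoter_sequence"))
  w_up <- min(probe$w, nchar(probe$upstream))
  w_dn <- min(probe$w, nchar(probe$downstream))
  jk <- paste0(substr(probe$upstream, nchar(probe$upstream) - w_up + 1L,
                      nchar(probe$upstream)),
               substr(probe$downstream, 1L, w_dn))
  if (grepl(jk, allele$seq, fixed = TRUE)) return(TRUE)
  # junction broken; does the probe hybridize at all?
  subj <- Biostrings::DNAString(if (nchar(allele$seq)) allele$seq else "N")
  hyb <- any(vapply(c(probe$upstream, probe$downstream), function(h) {
    mm <- max(2L, ceiling(0.2 * nchar(h)))
    Biostrings::countPattern(Biostrings::DNAString(h), subj,
                             max.mismatch = mm, with.indels = TRUE) > 0
  }, logical(1)))
  structure(FALSE,
            reason = if (hyb) "junction_mismatch" else "no_hybridization")
}

#' Expected probe signal over a set of gene copies
#'
#' The MLPA peak of a probe is proportional to the number of target copies
#' on which both half-probes ligate; this counts them. A probe whose
#' junction window is disrupted on a variant allele counts only the copies
#' without the variant.
#'
#' @param copies list of [promoter_sequence()] alleles carried by one
#'   individual (possibly empty).
#' @param probe a [half_probe_pair()].
#' @return integer count of ligation-competent copies.
#' @export
expected_probe_signal <- function(copies, probe) {
  if (!length(copies)) return(0L)
  sum(vapply(copies, function(a) isTRUE(ligation_success(probe, a)),
             logical(1)))
}

#' Read variants from a minimal VCF-like TSV
#'
#' Columns: `pos`, `ref`, `alt`, `label`; 1-based promoter coordinates
#' (negative upstream of the transcription start, no position 0).
#'
#' @param path file path.
#' @return list of [variant()] objects.
#' @export
read_variants_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  stopifnot(all(c("pos", "ref", "alt") %in% names(df)))
  if (!"label" %in% names(df)) df$label <- sprintf("%d%s>%s", df$pos, df$ref, df$alt)
  lapply(seq_len(nrow(df)), function(i)
    variant(df$pos[i], df$ref[i], df$alt[i], df$label[i]))
}
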