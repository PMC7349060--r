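#' Classify an InDel as SSR or non-SSR
#'
#' Finds the maximal tandem array (unit 1-6 bp, at least 3 copies spanning
#' the InDel) containing the inserted/deleted bases in their flanking
#' context. The InDel is SSR-type when the inserted/deleted sequence is a
#' whole number of repeat units (so the two alleles differ by >= 1 full
#' repeat). The motif is reported in canonical rotation: the
#' lexicographically smallest rotation over both strands, so the "TA" and
#' "AT" phasings of one array report the same motif.
#'
#' @param ref,alt VCF-style alleles (anchored; the shared leading base is
#'   trimmed internally).
#' @param left_flank,right_flank reference sequence immediately left/right
#'   of the InDel (>= 30 bp each recommended).
#' @return list: is_ssr, motif (canonical), unit (as phased), unit_len,
#'   copies_long, copies_short, delta_repeats.
#' @export
detect_ssr <- function(ref, alt, left_flank, right_flank) {
  tr <- trim_anchor(0L, ref, alt)
  ins <- nchar(tr$ref) == 0L
  del <- nchar(tr$alt) == 0L
  no <- list(is_ssr = FALSE, motif = NA_character_, unit = NA_character_,
             unit_len = NA_integer_, copies_long = NA_integer_,
             copies_short = NA_integer_, delta_repeats = NA_integer_)
  if (!ins && !del) return(no)                 # complex substitution
  s <- if (ins) tr$alt else tr$ref
  # the anchor bases trimmed from the front belong to the left context
  left <- paste0(left_flank, substr(ref, 1L, tr$pos))
  ctx <- paste0(left, s, right_flank)
  best <- NULL
  for (u in seq_len(min(6L, nchar(s)))) {
    if (nchar(s) %% u != 0L) next
    unit <- substr(s, 1L, u)
    if (s != strrep(unit, nchar(s) %/% u)) next
    a_start <- nchar(left) + 1L
    a_end <- nchar(left) + nchar(s)
    while (a_start - u >= 1L &&
           substring(ctx, a_start - u, a_start - 1L) ==
             substring(ctx, a_start, a_start + u - 1L))
      a_start <- a_start - u
    while (a_end + u <= nchar(ctx) &&
           substring(ctx, a_end + 1L, a_end + u) ==
             substring(ctx, a_end - u + 1L, a_end))
      a_end <- a_end + u
    copies_long <- (a_end - a_start + 1L) %/% u
    arr_len <- a_end - a_start + 1L
    if (is.null(best) || arr_len > best$arr_len)
      best <- list(u = u, unit = unit, copies_long = copies_long,
                   arr_len = arr_len)
  }
  if (is.null(best)) return(no)
  delta <- nchar(s) %/% best$u
  copies_short <- best$copies_long - delta
  if (best$copies_long < 3L || delta < 1L) return(no)
  list(is_ssr = TRUE, motif = canonical_motif(best$unit), unit = best$unit,
       unit_len = best$u, copies_long = best$copies_long,
       copies_short = copies_short, delta_repeats = delta)
}

#' Select informative InDel loci
#'
#' Keeps plain InDels whose net length change is at least \code{min_len}
#' (boundary inclusive; coded N) and SSR-type InDels whose alleles differ by
#' at least one full repeat unit, regardless of length (coded S).
#'
#' @param ds a (filtered) \code{variant_dataset}.
#' @param genome reference genome (a \code{toy_genome} or named character
#'   vector of sequences) supplying the flanking context for SSR detection.
#' @param min_len minimum net length change for non-SSR InDels (default 5).
#' @param flank flanking context width for SSR detection (default 30).
#' @return data.frame: site (row index into \code{ds$sites}), chrom, pos,
#'   ref, alt, net, class ("S"/"N"), motif, delta_repeats.
#' @export
select_candidate_indels <- function(ds, genome, min_len = 5L, flank = 30L) {
  stopifnot(inherits(ds, "variant_dataset"))
  seqs <- if (inherits(genome, "toy_genome")) genome$seq else genome
  idx <- which(ds$sites$class == "InDel")
  rows <- list()
  for (i in idx) {
    chrom <- ds$sites$chrom[i]; pos <- ds$sites$pos[i]
    ref <- ds$sites$ref[i]; alt <- ds$sites$alt[i]
    s <- seqs[[chrom]]
    lf <- substring(s, max(1L, pos - flank), pos - 1L)
    rf <- substring(s, pos + nchar(ref),
                    min(nchar(s), pos + nchar(ref) + flank - 1L))
    ssr <- detect_ssr(ref, alt, lf, rf)
    net <- nchar(alt) - nchar(ref)
    cls <- if (ssr$is_ssr && ssr$delta_repeats >= 1L) "S"
           else if (abs(net) >= min_len) "N"
           else NA_character_
    if (is.na(cls)) next
    rows[[length(rows) + 1L]] <- data.frame(
      site = i, chrom = chrom, pos = pos, ref = ref, alt = alt, net = net,
      class = cls, motif = ssr$motif,
      delta_repeats = ssr$delta_repeats %||% NA_integer_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows) %||%
    data.frame(site = integer(0), chrom = character(0), pos = integer(0),
               ref = character(0), alt = character(0), net = integer(0),
               class = character(0), motif = character(0),
               delta_repeats = integer(0))
  rownames(out) <- NULL
  out
}

#' Build the ~100-bp flanking query around an InDel
#'
#' Extracts a window of \code{window} bp centered on the InDel allele from
#' the chosen haplotype (alternative by default — the putatively
#' introgressed allele), splitting the flanks as evenly as the allele
#' allows. Near a chromosome end the window shifts toward the other side so
#' the total length stays \code{window} when possible; a chromosome shorter
#' than the window yields the whole chromosome with a warning. The query
#' coordinates of the InDel region (the allele plus one base past the
#' junction) are recorded for the InDel-region identity computation.
#'
#' @param genome \code{toy_genome} or named character vector of sequences.
#' @param locus list/row with chrom, pos, ref, alt.
#' @param window query length, bp (default 100).
#' @param allele "alt" (default) or "ref": which haplotype the query is
#'   built on.
#' @param edits optional data.frame (chrom, pos, ref, alt) of the carrier
#'   sample's other variants; those falling inside the window are applied so
#'   the query is the sample's local haplotype, not the reference with a
#'   single substitution (a genotype's flanking sequence carries all of its
#'   variants).
#' @return list: seq, indel_start, indel_end (query coordinates), chrom,
#'   pos, ref, alt, allele.
#' @export
extract_flank <- function(genome, locus, window = 100L,
                          allele = c("alt", "ref"), edits = NULL) {
  allele <- match.arg(allele)
  seqs <- if (inherits(genome, "toy_genome")) genome$seq else genome
  s <- seqs[[locus$chrom]]
  if (is.null(s)) stop_cfg("chromosome '%s' not in genome", locus$chrom)
  len <- nchar(s)
  a <- if (allele == "alt") locus$alt else locus$ref
  a_len <- nchar(a)

  # local haplotype: reference slab around the locus with the candidate
  # allele (and any supplied sample edits) applied
  slack <- window + 80L
  rs <- max(1L, locus$pos - slack)
  re <- min(len, locus$pos + nchar(locus$ref) - 1L + slack)
  local <- substring(s, rs, re)
  ed <- data.frame(pos = locus$pos, ref = locus$ref, alt = a,
                   stringsAsFactors = FALSE)
  if (!is.null(edits)) {
    other <- edits[edits$chrom == locus$chrom & edits$pos != locus$pos &
                     edits$pos >= rs &
                     edits$pos + nchar(edits$ref) - 1L <= re, ,
                   drop = FALSE]
    if (nrow(other))
      ed <- rbind(ed, other[c("pos", "ref", "alt")])
  }
  ed <- ed[order(-ed$pos), , drop = FALSE]
  for (r in seq_len(nrow(ed))) {
    lp <- ed$pos[r] - rs + 1L
    local <- paste0(substring(local, 1L, lp - 1L), ed$alt[r],
                    substring(local, lp + nchar(ed$ref[r])))
  }
  shift <- sum(ifelse(ed$pos < locus$pos,
                      nchar(ed$alt) - nchar(ed$ref), 0L))
  cand_start <- (locus$pos - rs + 1L) + shift
  llen <- nchar(local)

  left_avail <- cand_start - 1L
  right_avail <- llen - (cand_start + a_len - 1L)
  if (a_len + left_avail + right_avail < window &&
      (rs == 1L && re == len)) {
    warning(sprintf("chromosome %s shorter than the %d-bp window; using all of it",
                    locus$chrom, window), call. = FALSE)
    left_n <- left_avail
    right_n <- right_avail
  } else {
    left_n <- (window - a_len) %/% 2L
    right_n <- window - a_len - left_n
    if (left_n > left_avail) {              # shift right near the start
      right_n <- right_n + (left_n - left_avail)
      left_n <- left_avail
    } else if (right_n > right_avail) {     # shift left near the end
      left_n <- left_n + (right_n - right_avail)
      right_n <- right_avail
    }
    right_n <- min(right_n, llen - (cand_start + a_len - 1L))
  }
  q <- substring(local, cand_start - left_n,
                 cand_start + a_len - 1L + right_n)
  list(seq = q,
       indel_start = left_n + 1L,
       indel_end = min(nchar(q), left_n + a_len + 1L),
       chrom = locus$chrom, pos = locus$pos,
       ref = locus$ref, alt = locus$alt, allele = allele)
}

#' Exact k-mer index of a sequence
#' @param s sequence string.
#' @param k k-mer length.
#' @return list mapping k-mer to start positions.
#' @export
kmer_index <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(list())
  starts <- seq_len(n - k + 1L)
  kmers <- substring(s, starts, starts + k - 1L)
  split(starts, kmers)
}

score_sub <- function(a, b) ifelse(a == b, 1, -1)

#' Banded global (fitting) alignment with affine gaps
#'
#' Gotoh dynamic programming of the full query against a subject window,
#' with free leading/trailing subject gaps (the query must align end to
#' end), match +1, mismatch -1, gap open -2, gap extend -1 (a gap of length
#' L scores -(2 + L)), restricted to a diagonal band. Returns the score and
#' the aligned column list for identity computations.
#'
#' @param query,subject sequence strings.
#' @param band band half-width around the main diagonal; \code{Inf} gives
#'   the full (unbanded) dynamic program.
#' @param diag0 expected diagonal offset (subject position minus query
#'   position) at the band center.
#' @return list: score, columns (data.frame qi, si, type in
#'   M/I(query-only)/D(subject-only)), subject_start, subject_end.
#' @export
banded_align <- function(query, subject, band = Inf, diag0 = 0L) {
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  s <- strsplit(subject, "", fixed = TRUE)[[1]]
  m <- length(q); n <- length(s)
  NEG <- -1e9
  GO <- 2; GE <- 1
  M <- X <- Y <- matrix(NEG, m + 1L, n + 1L)
  M[1L, ] <- 0                                 # free leading subject gaps
  X[, 1L] <- -(GO + GE * (0:m))
  X[1L, 1L] <- NEG
  jseq <- 0:n
  for (i in seq_len(m)) {
    lo <- if (is.finite(band)) max(0L, i + diag0 - band) else 0L
    hi <- if (is.finite(band)) min(n, i + diag0 + band) else n
    prevM <- M[i, ]; prevX <- X[i, ]; prevY <- Y[i, ]
    prev_best <- pmax(prevM, prevX, prevY)
    mrow <- xrow <- yrow <- rep(NEG, n + 1L)
    js <- seq_len(n)
    mrow[js + 1L] <- prev_best[js] + score_sub(q[i], s[js])
    xrow[js + 1L] <- pmax(prevM[js + 1L] - GO - GE,
                          prevX[js + 1L] - GE,
                          prevY[js + 1L] - GO - GE)
    xrow[1L] <- X[i + 1L, 1L]
    # mask the band before the horizontal scan
    mask <- jseq < lo | jseq > hi
    mrow[mask] <- NEG
    xrow[mask] <- NEG
    # yrow[j] = max_{j0 < j} max(mrow, xrow)[j0] - GO - GE*(j - j0)
    a <- pmax(mrow, xrow) + GE * jseq
    cm <- cummax(a)
    yrow[js + 1L] <- cm[js] - GE * (js) - GO
    yrow[mask] <- NEG
    M[i + 1L, ] <- mrow
    X[i + 1L, ] <- xrow
    Y[i + 1L, ] <- yrow
  }
  # free trailing subject gaps: end anywhere in the last row
  last <- pmax(M[m + 1L, ], X[m + 1L, ], Y[m + 1L, ])
  j <- which.max(last) - 1L
  score <- last[j + 1L]
  state <- c("M", "X", "Y")[which.max(c(M[m + 1L, j + 1L],
                                        X[m + 1L, j + 1L],
                                        Y[m + 1L, j + 1L]))]
  cols <- list()
  i <- m
  subject_end <- j
  tol <- 1e-6
  while (i > 0L) {
    if (j == 0L) state <- "X"   # only query-gap moves exist at column 0
    if (state == "M") {
      cols[[length(cols) + 1L]] <- c(i, j, 1L)  # 1 = M
      sc <- score_sub(q[i], s[j])
      v <- M[i + 1L, j + 1L] - sc
      state <- if (abs(M[i, j] - v) < tol) "M"
               else if (abs(X[i, j] - v) < tol) "X" else "Y"
      i <- i - 1L; j <- j - 1L
    } else if (state == "X") {                   # gap in subject, query base
      cols[[length(cols) + 1L]] <- c(i, NA, 2L)  # 2 = I
      v <- X[i + 1L, j + 1L]
      state <- if (abs(X[i, j + 1L] - GE - v) < tol) "X"
               else if (abs(M[i, j + 1L] - GO - GE - v) < tol) "M" else "Y"
      i <- i - 1L
    } else {                                     # gap in query, subject base
      cols[[length(cols) + 1L]] <- c(i, j, 3L)   # 3 = D
      v <- Y[i + 1L, j + 1L]
      state <- if (abs(Y[i + 1L, j] - GE - v) < tol) "Y"
               else if (abs(M[i + 1L, j] - GO - GE - v) < tol) "M" else "X"
      j <- j - 1L
    }
  }
  colm <- do.call(rbind, rev(cols))
  columns <- data.frame(qi = colm[, 1L], si = colm[, 2L],
                        type = c("M", "I", "D")[colm[, 3L]])
  si_ok <- columns$si[!is.na(columns$si)]
  list(score = score, columns = columns,
       subject_start = if (length(si_ok)) min(si_ok) else NA_integer_,
       subject_end = subject_end)
}

alignment_identities <- function(columns, q, s, region) {
  is_match <- columns$type == "M" &
    substring(q, columns$qi, columns$qi) ==
      substring(s, columns$si, columns$si)
  overall <- 100 * sum(is_match) / nrow(columns)
  # a column belongs to the InDel region if it consumes a query base inside
  # [r1, r2], or is a subject-only column strictly inside the region
  qi_eff <- columns$qi
  in_region <- ifelse(columns$type == "D",
                      qi_eff >= region[1L] & qi_eff < region[2L],
                      qi_eff >= region[1L] & qi_eff <= region[2L])
  n_reg <- sum(in_region)
  indel_id <- if (n_reg == 0L) NA_real_
              else 100 * sum(is_match & in_region) / n_reg
  c(overall = overall, indel = indel_id)
}

#' Seed-and-extend alignment of a flank query against a wild genome
#'
#' Exact k-mer seeds (k = 15 on both strands; when no 15-mer seeds, an
#' 11-mer rescue pass) locate candidate windows, each globally aligned to
#' the full query with the banded affine-gap dynamic program of
#' \code{\link{banded_align}} (band = 2 x InDel allele length + 10).
#' Overall identity is matches over aligned columns; InDel-region identity
#' is computed over the columns spanning the query's InDel interval. Hits
#' are sorted by overall identity.
#'
#' @param query a \code{\link{extract_flank}} result.
#' @param wild_seqs named character vector of the wild genome's chromosome
#'   sequences.
#' @param species label carried into the hits.
#' @param k seed length (default 15; rescue pass at 11).
#' @param indices optional precomputed per-chromosome k-mer indices (list
#'   chrom -> \code{\link{kmer_index}}), keyed by the same k.
#' @param indices11 optional precomputed 11-mer indices for the rescue pass.
#' @return data.frame of hits: species, chrom, start, strand,
#'   overall_identity, indel_identity, aligned_cols, score.
#' @export
align_query <- function(query, wild_seqs, species = NA_character_,
                        k = 15L, indices = NULL, indices11 = NULL) {
  qlen <- nchar(query$seq)
  band <- 2L * max(1L, query$indel_end - query$indel_start + 1L) + 10L
  strands <- list(`+` = query$seq, `-` = revcomp_chr(query$seq))
  hits <- list()
  for (chrom in names(wild_seqs)) {
    subj <- wild_seqs[[chrom]]
    idx <- if (!is.null(indices) && !is.null(indices[[chrom]]))
      indices[[chrom]] else kmer_index(subj, k)
    idx11 <- if (!is.null(indices11)) indices11[[chrom]] else NULL
    for (strand in names(strands)) {
      qs <- strands[[strand]]
      diags <- seed_diagonals(qs, idx, k)
      if (length(diags) == 0L && k > 11L) {
        if (is.null(idx11)) idx11 <- kmer_index(subj, 11L)
        diags <- seed_diagonals(qs, idx11, 11L)
      }
      if (length(diags) == 0L) next
      diags <- cluster_diagonals(diags, band)
      for (d in diags) {
        ws <- max(1L, d + 1L - band)
        we <- min(nchar(subj), d + qlen + band)
        window <- substring(subj, ws, we)
        d_local <- d - (ws - 1L)
        aln <- banded_align(qs, window, band = band, diag0 = d_local)
        if (is.na(aln$subject_start)) next   # degenerate: nothing aligned
        region <- if (strand == "+") {
          c(query$indel_start, query$indel_end)
        } else {
          c(qlen - query$indel_end + 1L, qlen - query$indel_start + 1L)
        }
        ids <- alignment_identities(aln$columns, qs, window, region)
        hits[[length(hits) + 1L]] <- data.frame(
          species = species, chrom = chrom,
          start = ws + aln$subject_start - 1L, strand = strand,
          overall_identity = ids[["overall"]],
          indel_identity = ids[["indel"]],
          aligned_cols = nrow(aln$columns), score = aln$score,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, hits) %||%
    data.frame(species = character(0), chrom = character(0),
               start = integer(0), strand = character(0),
               overall_identity = numeric(0), indel_identity = numeric(0),
               aligned_cols = integer(0), score = numeric(0))
  out <- out[order(-out$overall_identity), , drop = FALSE]
  # collapse near-duplicate hits (same chrom/strand, overlapping placement)
  if (nrow(out) > 1L) {
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))[-1L]) {
      prior <- out[seq_len(i - 1L), ][keep[seq_len(i - 1L)], , drop = FALSE]
      dup <- prior$chrom == out$chrom[i] & prior$strand == out$strand[i] &
        abs(prior$start - out$start[i]) < qlen
      if (any(dup)) keep[i] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

seed_diagonals <- function(qs, idx, k) {
  qlen <- nchar(qs)
  if (qlen < k) return(integer(0))
  starts <- seq_len(qlen - k + 1L)
  kmers <- substring(qs, starts, starts + k - 1L)
  m <- match(kmers, names(idx))
  hit <- which(!is.na(m))
  if (length(hit) == 0L) return(integer(0))
  unique(unlist(lapply(hit, function(i) idx[[m[i]]] - starts[i]),
                use.names = FALSE))
}

cluster_diagonals <- function(diags, band) {
  diags <- sort(diags)
  groups <- cumsum(c(1L, diff(diags) > band))
  vapply(split(diags, groups), function(g) g[ceiling(length(g) / 2)],
         integer(1))
}

#' Assign a putative wild-species origin to an InDel locus
#'
#' A species passes when its best hit shows 100% identity over the InDel
#' region and more than 90% (strict) overall identity over the full query.
#' Exactly one passing species gives status "assigned"; two or more give
#' "ambiguous" (ties are never broken silently); none gives "unassigned".
#'
#' @param hits data.frame of hits over all species (see
#'   \code{\link{align_query}}), best hit first within species.
#' @param species_names all configured species (species without hits count
#'   as failing).
#' @param overall_min overall identity threshold, percent, strict
#'   (default 90).
#' @return list: status, species (passing labels), best (per-species best
#'   hit data.frame).
#' @export
assign_origin <- function(hits, species_names, overall_min = 90) {
  best <- do.call(rbind, lapply(species_names, function(sp) {
    h <- hits[hits$species == sp, , drop = FALSE]
    if (nrow(h) == 0L)
      return(data.frame(species = sp, chrom = NA_character_,
                        start = NA_integer_, strand = NA_character_,
                        overall_identity = NA_real_,
                        indel_identity = NA_real_,
                        aligned_cols = NA_integer_, score = NA_real_,
                        stringsAsFactors = FALSE))
    h[1L, c("species", "chrom", "start", "strand", "overall_identity",
            "indel_identity", "aligned_cols", "score")]
  }))
  rownames(best) <- NULL
  pass <- !is.na(best$overall_identity) &
    !is.na(best$indel_identity) &
    best$indel_identity == 100 &
    best$overall_identity > overall_min
  status <- if (sum(pass) == 1L) "assigned"
            else if (sum(pass) >= 2L) "ambiguous" else "unassigned"
  list(status = status, species = best$species[pass], best = best)
}

#' Scan a sample's candidate InDels for wild-relative origin
#'
#' End-to-end wrapper: select the sample's informative InDels, build the
#' 100-bp flank queries on the alternative-allele haplotype, align each
#' against every wild genome, and apply the dual identity rule.
#'
#' @param ds a (filtered) \code{variant_dataset}.
#' @param genome the reference genome.
#' @param wild_genomes named list: species -> named character vector of
#'   chromosome sequences.
#' @param sample sample whose alt-carrying InDels are scanned.
#' @param min_len,window see \code{\link{select_candidate_indels}} and
#'   \code{\link{extract_flank}}.
#' @param allele haplotype the queries are built on ("alt" default).
#' @return list: candidates, assignments (one row per candidate: locus,
#'   class, status, assigned species), hits (all alignment hits).
#' @export
scan_introgressions <- function(ds, genome, wild_genomes, sample,
                                min_len = 5L, window = 100L,
                                allele = "alt") {
  stopifnot(sample %in% ds$samples)
  cand <- select_candidate_indels(ds, genome, min_len = min_len)
  samp_i <- match(sample, ds$samples)
  carried <- !is.na(ds$calls[cand$site, samp_i]) &
    ds$calls[cand$site, samp_i] >= 1L
  cand <- cand[carried, , drop = FALSE]
  k <- 15L
  indices <- lapply(wild_genomes, function(ws)
    lapply(ws, kmer_index, k = k))
  indices11 <- lapply(wild_genomes, function(ws)
    lapply(ws, kmer_index, k = 11L))
  # queries are the sample's local haplotype: its other carried variants
  # inside each window are applied alongside the candidate allele
  carried_all <- !is.na(ds$calls[, samp_i]) & ds$calls[, samp_i] >= 1L
  sample_edits <- ds$sites[carried_all, c("chrom", "pos", "ref", "alt")]
  rows <- list(); all_hits <- list()
  for (r in seq_len(nrow(cand))) {
    locus <- as.list(cand[r, ])
    q <- extract_flank(genome, locus, window = window, allele = allele,
                       edits = sample_edits)
    hits <- do.call(rbind, lapply(names(wild_genomes), function(sp)
      align_query(q, wild_genomes[[sp]], species = sp, k = k,
                  indices = indices[[sp]], indices11 = indices11[[sp]])))
    asg <- assign_origin(hits, names(wild_genomes))
    all_hits[[length(all_hits) + 1L]] <- hits
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = locus$chrom, pos = locus$pos, class = locus$class,
      motif = locus$motif, status = asg$status,
      species = paste(asg$species, collapse = ","),
      stringsAsFactors = FALSE)
  }
  list(candidates = cand,
       assignments = do.call(rbind, rows) %||%
         data.frame(chrom = character(0), pos = integer(0),
                    class = character(0), motif = character(0),
                    status = character(0), species = character(0)),
       hits = do.call(rbind, all_hits) %||% data.frame())
}
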