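# Subcloning-enzyme selection and in-silico plasmid assembly. Uniqueness
# checks on plasmids (backbone or assembled) use circular topology; checks on
# the bare insert use linear topology.

#' Vector backbone container
#'
#' @param seq Circular backbone sequence (A/C/G/T).
#' @param mcs Length-2 integer vector: the multiple-cloning-site interval in
#'   backbone coordinates, 0-based half-open.
#' @param features Optional feature tibble (e.g. marker annotations).
#' @param name Backbone name.
#' @return An object of class `pipo_backbone`.
#' @export
backbone <- function(seq, mcs, features = empty_features(), name = "backbone") {
  seq <- as_dna(seq, "backbone sequence")
  mcs <- as.integer(mcs)
  n <- nchar(seq)
  if (length(mcs) != 2L || mcs[2] <= mcs[1] || mcs[1] < 0L || mcs[2] > n) {
    stop("MCS interval must be a nonempty 0-based half-open interval within ",
         "the backbone [0, ", n, ")", call. = FALSE)
  }
  structure(list(seq = seq, mcs = mcs, features = features, name = name,
                 topology = "circular"),
            class = "pipo_backbone")
}

#' @export
print.pipo_backbone <- function(x, ...) {
  cat(sprintf("<pipo_backbone> %s: %d bp circular, MCS [%d, %d)\n",
              x$name, nchar(x$seq), x$mcs[1], x$mcs[2]))
  invisible(x)
}

#' Select the subcloning (MCS) enzyme pair
#'
#' Chooses the first pair, in enzyme file order, of distinct enzymes such that
#' each cuts the backbone exactly once (circular scan), its recognition site
#' lies wholly inside the MCS interval, it does not cut the insert, and it is
#' not the linearization enzyme. The pair is oriented left/right by backbone
#' cut coordinate. The assembled plasmid is additionally required to carry the
#' linearization site exactly once and each tag-flanking site exactly once;
#' pairs failing these are passed over.
#'
#' @param insert An assembled insert ([annotated_seq]).
#' @param bb A [backbone()] object.
#' @param params A `pipo_params` object.
#' @param linearization_enzyme Name of the candidate's linearization enzyme.
#' @param tag_sites Character vector of assigned tag enzyme names (may be
#'   empty for deletions).
#' @param bb_hits Optional precomputed circular backbone site table
#'   (`find_sites(bb$seq, params$enzymes, "circular")`; performance).
#' @return On success, list with `left`, `right` (enzyme names) and `plasmid`
#'   (a `pipo_plasmid`); on failure, list with `reason` (coded) and `detail`.
#' @export
select_mcs_enzymes <- function(insert, bb, params, linearization_enzyme,
                               tag_sites = character(0), bb_hits = NULL) {
  stopifnot(inherits(bb, "pipo_backbone"))
  enz <- params$enzymes
  lin_row <- enz[enz$name == linearization_enzyme, , drop = FALSE]
  if (is.null(bb_hits)) bb_hits <- find_sites(bb$seq, enz, "circular")

  eligible <- list()
  for (i in seq_len(nrow(enz))) {
    nm <- enz$name[[i]]
    if (identical(nm, linearization_enzyme)) next
    recog <- enz$recognition[[i]]
    hits <- bb_hits[bb_hits$enzyme == nm, , drop = FALSE]
    if (nrow(hits) != 1L) next
    if (hits$start[[1]] < bb$mcs[1] ||
        hits$start[[1]] + nchar(recog) > bb$mcs[2]) next
    if (count_one(insert$seq, recog, "linear") > 0L) next
    eligible[[length(eligible) + 1L]] <- list(name = nm, cut = hits$cut[[1]])
  }
  if (length(eligible) < 2L) {
    return(list(reason = "MCS_PAIR_UNAVAILABLE",
                detail = sprintf("only %d usable MCS enzyme(s) in the backbone",
                                 length(eligible))))
  }

  tag_recogs <- if (length(tag_sites) > 0) {
    params$tag_flank_enzymes$recognition[match(tag_sites,
                                               params$tag_flank_enzymes$name)]
  } else character(0)

  blockers <- character(0)
  for (i in seq_len(length(eligible) - 1L)) {
    for (j in seq.int(i + 1L, length(eligible))) {
      a <- eligible[[i]]; b <- eligible[[j]]
      if (a$cut == b$cut) next
      left <- if (a$cut < b$cut) a else b
      right <- if (a$cut < b$cut) b else a
      plasmid <- assemble_plasmid(bb, insert, c(left$name, right$name), params,
                                  bb_hits = bb_hits)
      if (count_one(plasmid$circle, lin_row$recognition[[1]], "circular") != 1L) {
        blockers <- c(blockers, "LINEARIZATION_NOT_UNIQUE")
        next
      }
      tag_bad <- FALSE
      for (tr in tag_recogs) {
        if (count_one(plasmid$circle, tr, "circular") != 1L) { tag_bad <- TRUE; break }
      }
      if (tag_bad) {
        blockers <- c(blockers, "TAG_SITES_UNAVAILABLE")
        next
      }
      return(list(left = left$name, right = right$name, plasmid = plasmid))
    }
  }
  reason <- if ("LINEARIZATION_NOT_UNIQUE" %in% blockers) {
    "LINEARIZATION_NOT_UNIQUE"
  } else if ("TAG_SITES_UNAVAILABLE" %in% blockers) {
    "TAG_SITES_UNAVAILABLE"
  } else {
    "MCS_PAIR_UNAVAILABLE"
  }
  list(reason = reason,
       detail = "no MCS enzyme pair keeps all plasmid sites unique")
}

#' Assemble the circular PIPO plasmid
#'
#' Simulates the double digest of the backbone at the two MCS cut coordinates
#' and ligation of the insert in place of the excised MCS fragment. The insert
#' is oriented so that the pop-out arm sits adjacent to the left
#' (lower-coordinate) MCS site; features are carried over with shifted
#' coordinates.
#'
#' @param bb A [backbone()] object.
#' @param insert An assembled insert ([annotated_seq]).
#' @param mcs_pair Character vector `c(left, right)` of enzyme names (left =
#'   lower backbone cut coordinate).
#' @param params A `pipo_params` object (supplies the enzyme table).
#' @param bb_hits Optional precomputed circular backbone site table
#'   (performance).
#' @return A `pipo_plasmid`: circular [annotated_seq]-like object with `seq`
#'   (backbone coordinates), `features`, plus the genomic-orientation rotation
#'   `circle` used for linearization (`cut_in_circle` marks the linearization
#'   cut).
#' @export
assemble_plasmid <- function(bb, insert, mcs_pair, params, bb_hits = NULL) {
  enz <- params$enzymes
  if (is.null(bb_hits)) bb_hits <- find_sites(bb$seq, enz, "circular")
  cut_of <- function(nm) {
    hits <- bb_hits[bb_hits$enzyme == nm, , drop = FALSE]
    if (nrow(hits) != 1L) {
      stop("MCS enzyme ", nm, " does not cut the backbone exactly once",
           call. = FALSE)
    }
    hits$cut[[1]]
  }
  lc <- cut_of(mcs_pair[[1]])
  rc <- cut_of(mcs_pair[[2]])
  if (lc >= rc) stop("MCS pair is not ordered left < right", call. = FALSE)
  n <- nchar(bb$seq)
  I <- nchar(insert$seq)

  pout <- get_feature(insert, "POP_OUT_ARM")
  pin <- get_feature(insert, "POP_IN_ARM")
  forward <- pout$start < pin$start

  ins_seq <- if (forward) insert$seq else dna_revcomp(insert$seq)
  plasmid_seq <- paste0(subseq0(bb$seq, 0L, lc), ins_seq, subseq0(bb$seq, rc, n))

  # features in plasmid (backbone) coordinates
  shift_ins <- function(f) {
    if (forward) {
      f$start <- f$start + lc; f$end <- f$end + lc
    } else {
      s <- lc + (I - f$end); e <- lc + (I - f$start)
      f$start <- s; f$end <- e
      f$strand <- ifelse(f$strand == "+", "-", "+")
    }
    f
  }
  feats <- shift_ins(insert$features)
  if (nrow(bb$features) > 0) {
    keep_left <- bb$features[bb$features$end <= lc, , drop = FALSE]
    keep_right <- bb$features[bb$features$start >= rc, , drop = FALSE]
    keep_right$start <- keep_right$start + (lc + I - rc)
    keep_right$end <- keep_right$end + (lc + I - rc)
    feats <- dplyr::bind_rows(feats, keep_left, keep_right)
  }

  # genomic-orientation reading of the same circle, starting at the insert:
  # insert + retained backbone arc (reverse-complemented when the insert was
  # placed in reverse)
  bb_rest <- paste0(subseq0(bb$seq, rc, n), subseq0(bb$seq, 0L, lc))
  circle <- paste0(insert$seq, if (forward) bb_rest else dna_revcomp(bb_rest))
  circle_feats <- dplyr::bind_rows(
    insert$features,
    feature_row("BACKBONE", I, nchar(circle)))

  structure(list(seq = plasmid_seq, features = feats, topology = "circular",
                 circle = circle, circle_features = circle_feats,
                 cut_in_circle = attr(insert, "cut_in_insert"),
                 insert_len = I, insert_forward = forward,
                 backbone_len = n, excised_len = rc - lc,
                 left_cut = lc, right_cut = rc),
            class = c("pipo_plasmid", "annotated_seq"))
}

#' Open the assembled plasmid at its linearization cut site
#'
#' Returns the linear transformation-ready molecule in genomic orientation:
#' it begins with the pop-in homology downstream of the cut and ends with the
#' pop-in homology upstream of it.
#'
#' @param plasmid A `pipo_plasmid` from [assemble_plasmid()].
#' @return A linear [annotated_seq] whose features (`POP_OUT_ARM`,
#'   `BACKBONE`, ...) are rotated into linear coordinates.
#' @export
linearize_plasmid <- function(plasmid) {
  stopifnot(inherits(plasmid, "pipo_plasmid"))
  ci <- plasmid$cut_in_circle
  circ <- plasmid$circle
  n <- nchar(circ)
  linear <- paste0(subseq0(circ, ci, n), subseq0(circ, 0L, ci))
  f <- plasmid$circle_features
  rot <- function(p) ifelse(p >= ci, p - ci, p - ci + n)
  spans_cut <- f$start < ci & f$end > ci
  f <- f[!spans_cut, , drop = FALSE]          # the pop-in arm spans the cut
  f$start <- as.integer(rot(f$start))
  # interval ends: rotate the last covered base, then +1
  f$end <- as.integer(rot(f$end - 1L) + 1L)
  annotated_seq(linear, f, "linear")
}
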