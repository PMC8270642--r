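#' Weighted total of match-gene hits
#'
#' Each match i occurs in w_i contigs and has n_i unique match-gene hit
#' pairs against a gene database; the weighted total is
#' \deqn{H = \sum_i w_i n_i,} so matches present in many contigs count
#' proportionally more.
#'
#' @param w Integer vector of per-match contig multiplicities (w_i >= 1).
#' @param n Integer vector of per-match unique hit counts (n_i >= 0).
#' @return Numeric H.
#' @examples
#' weightedHits(c(2, 3), c(1, 4)) # 14
#' @export
weightedHits <- function(w, n) {
    stopifnot(length(w) == length(n))
    if (length(w) == 0L) return(0)
    stopifnot(all(w >= 1), all(n >= 0))
    sum(as.numeric(w) * as.numeric(n))
}

#' Standard error of the weighted hit total
#'
#' Under random sampling of organisms the standard error of H is, in the
#' default reading, \deqn{\delta H = \sqrt{\sum_i w_i n_i^2}.} The radical
#' placement admits an alternative reading
#' \eqn{\sqrt{\sum_i (w_i n_i)^2}}, selectable via \code{method}; outputs
#' always name the formula used.
#'
#' @param w,n As in [weightedHits()].
#' @param method "sqrt_sum_w_n2" (default, \eqn{\sqrt{\sum w_i n_i^2}}) or
#'   "sqrt_sum_wn_2" (\eqn{\sqrt{\sum (w_i n_i)^2}}).
#' @return Numeric delta H, with attribute \code{"method"}.
#' @export
hitsStderr <- function(w, n, method = c("sqrt_sum_w_n2", "sqrt_sum_wn_2")) {
    method <- match.arg(method)
    stopifnot(length(w) == length(n))
    out <- if (length(w) == 0L) 0 else {
        stopifnot(all(w >= 1), all(n >= 0))
        switch(method,
               sqrt_sum_w_n2 = sqrt(sum(as.numeric(w) * as.numeric(n)^2)),
               sqrt_sum_wn_2 = sqrt(sum((as.numeric(w) * as.numeric(n))^2)))
    }
    attr(out, "method") <- method
    out
}

#' Sample length-matched control sequences
#'
#' For each match, draws one subsequence of exactly the match length from
#' each of its source contigs, at a uniformly random start position.
#' Sampling is without replacement at the level of start positions: within
#' one run no two control sequences share the same (contig, start) pair.
#' Intervals may overlap. The control set thereby mirrors both the length
#' distribution and the per-species representation of the observed set.
#'
#' @param matches \code{data.frame} with columns \code{match_id},
#'   \code{length} (bp) and \code{contig_id}, one row per (match, source
#'   contig) pair — a match in w contigs has w rows.
#' @param contigSet A [ContigSet-class] holding the source contigs.
#' @param seed Optional integer seed for reproducible sampling.
#' @param maxTries Bounded retries per draw before failing (default 100).
#' @return \code{data.frame} with columns \code{match_id},
#'   \code{contig_id}, \code{start}, \code{length}, \code{sequence}.
#' @export
sampleControl <- function(matches, contigSet, seed = NULL,
                          maxTries = 100L) {
    stopifnot(is.data.frame(matches), is(contigSet, "ContigSet"),
              all(c("match_id", "length", "contig_id") %in%
                  names(matches)))
    if (!is.null(seed)) set.seed(seed)
    seqs <- contigs(contigSet)
    widths <- stats::setNames(Biostrings::width(seqs), names(seqs))
    used <- new.env(parent = emptyenv())
    rows <- vector("list", nrow(matches)); nr <- 0L
    for (i in seq_len(nrow(matches))) {
        cid <- as.character(matches$contig_id[i])
        len <- as.integer(matches$length[i])
        if (!cid %in% names(widths)) stop("unknown contig: ", cid)
        if (widths[cid] < len) {
            warning("contig ", cid, " shorter than match length ", len,
                    ": skipped")
            next
        }
        nStarts <- widths[cid] - len + 1L
        start <- NA_integer_
        for (try in seq_len(maxTries)) {
            s <- sample.int(nStarts, 1L)
            key <- paste0(cid, ":", s)
            if (is.null(used[[key]])) {
                used[[key]] <- TRUE; start <- s; break
            }
        }
        if (is.na(start))
            stop("contig ", cid, " exhausted: cannot sample an unused ",
                 "start position after ", maxTries, " tries")
        nr <- nr + 1L
        rows[[nr]] <- data.frame(
            match_id = as.character(matches$match_id[i]),
            contig_id = cid, start = start, length = len,
            sequence = as.character(Biostrings::subseq(
                seqs[[cid]], start, width = len)),
            stringsAsFactors = FALSE)
    }
    if (!nr) return(data.frame(match_id = character(),
                               contig_id = character(), start = integer(),
                               length = integer(), sequence = character(),
                               stringsAsFactors = FALSE))
    do.call(rbind, rows[seq_len(nr)])
}

#' Enrichment of weighted hits relative to a control set
#'
#' Ratio of the weighted hit totals of an observed and a control match
#' set, with a first-order error interval propagated from the two
#' standard errors:
#' \deqn{\delta(H_o/H_c) = (H_o/H_c)
#'   \sqrt{(\delta H_o/H_o)^2 + (\delta H_c/H_c)^2}.}
#'
#' @param wObs,nObs Weights and hit counts of the observed set.
#' @param wCtrl,nCtrl Weights and hit counts of the control set.
#' @param method Standard-error reading, see [hitsStderr()].
#' @return An [EnrichmentResult-class]; the ratio is \code{NA} when the
#'   control total is 0.
#' @export
enrichmentRatio <- function(wObs, nObs, wCtrl, nCtrl,
                            method = c("sqrt_sum_w_n2", "sqrt_sum_wn_2")) {
    method <- match.arg(method)
    Ho <- weightedHits(wObs, nObs)
    Hc <- weightedHits(wCtrl, nCtrl)
    dHo <- as.numeric(hitsStderr(wObs, nObs, method))
    dHc <- as.numeric(hitsStderr(wCtrl, nCtrl, method))
    if (Hc > 0) {
        ratio <- Ho / Hc
        dRatio <- if (Ho > 0)
            ratio * sqrt((dHo / Ho)^2 + (dHc / Hc)^2) else dHo / Hc
        interval <- c(ratio - dRatio, ratio + dRatio)
    } else {
        ratio <- NA_real_; interval <- c(NA_real_, NA_real_)
    }
    new("EnrichmentResult", HObserved = Ho, HControl = Hc,
        deltaHObserved = dHo, deltaHControl = dHc, ratio = ratio,
        ratioInterval = interval, stderrMethod = method)
}
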