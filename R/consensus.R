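# Consensus pathogenicity aggregation.
#
# Mirrors the ClinVar-style evidence model: per-submitter assertions on the
# five ACMG terms (P, LP, VUS, LB, B) are restricted to a trusted-submitter
# list and collapsed per variant. Two or more trusted submitters who all
# assert P/LP make a consensus pathogenic call; unanimous LB/B makes
# consensus benign; any mixture is conflicting; a lone trusted P/LP is
# carried as single-submitter pathogenic and must be resolved by an external
# adjudication table (the ACMG criteria evaluation itself is out of scope).

CLASSIFICATION_LEVELS <- c("P", "LP", "VUS", "LB", "B")

#' Aggregate per-submitter assertions into consensus calls
#'
#' @param submissions Data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `submitter`, `classification` (values among `P`, `LP`, `VUS`, `LB`,
#'   `B`; records with other values are dropped with a warning). One record
#'   per (variant, submitter) pair.
#' @param trusted Character vector of trusted submitter names; assertions
#'   from other submitters are ignored.
#' @return Data frame with one row per variant: `chrom`, `pos`, `ref`,
#'   `alt`, `key`, `n_trusted`, and `status` among `consensus_pathogenic`,
#'   `single_submitter_pathogenic`, `conflicting`, `consensus_benign`,
#'   `no_trusted_assertion`.
#' @export
consensus_classification <- function(submissions, trusted) {
  stopifnot(is.data.frame(submissions))
  s <- submissions
  bad <- !(s$classification %in% CLASSIFICATION_LEVELS)
  if (any(bad)) {
    warning("dropping ", sum(bad), " assertion(s) outside the five-level ",
            "classification vocabulary")
    s <- s[!bad, , drop = FALSE]
  }
  s$key <- variant_key(s$chrom, s$pos, s$ref, s$alt)
  if (anyDuplicated(paste(s$key, s$submitter)))
    stop("duplicate (variant, submitter) assertion records")

  all_keys <- unique(s$key)
  st <- s[s$submitter %in% trusted, , drop = FALSE]

  status_of <- function(cls) {
    n <- length(cls)
    if (n == 0L) return("no_trusted_assertion")
    path <- cls %in% c("P", "LP")
    ben <- cls %in% c("LB", "B")
    if (n == 1L) {
      if (path) return("single_submitter_pathogenic")
      return("no_trusted_assertion")  # a lone VUS/LB/B asserts nothing
    }
    if (all(path)) return("consensus_pathogenic")
    if (all(ben)) return("consensus_benign")
    if (any(path)) return("conflicting")  # P/LP mixed with VUS/LB/B
    "no_trusted_assertion"  # e.g. several VUS: nothing asserted either way
  }

  grp <- split(st$classification, st$key)
  status <- vapply(all_keys, function(k) {
    status_of(grp[[k]] %||% character(0))
  }, character(1))
  n_trusted <- vapply(all_keys, function(k) length(grp[[k]] %||% character(0)),
                      integer(1))

  first <- s[!duplicated(s$key), c("chrom", "pos", "ref", "alt", "key")]
  first <- first[match(all_keys, first$key), , drop = FALSE]
  first$n_trusted <- n_trusted
  first$status <- unname(status)
  rownames(first) <- NULL
  first
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble the analysis pathogenic set
#'
#' The pathogenic set is the union of (a) consensus pathogenic variants, (b)
#' single-submitter or conflicting variants externally adjudicated P/LP, and
#' (c) NMD-triggering variants in genes where loss of protein function is
#' the established disease mechanism (expected pathogenic by variant type
#' even without assertions). Each member carries provenance tags.
#'
#' @param calls Consensus calls from [consensus_classification()].
#' @param adjudications Optional data frame with `chrom`, `pos`, `ref`,
#'   `alt`, `classification` resolving single-submitter/conflicting
#'   variants. Adjudications of variants already at consensus are ignored
#'   with a warning (consensus wins).
#' @param nmd Optional annotated variant table with `chrom`, `pos`, `ref`,
#'   `alt`, `gene`, `nmd_status` (e.g. from [annotate_nmd()]).
#' @param lof_mechanism_genes Character vector of genes with an established
#'   loss-of-function disease mechanism; route (c) only applies to these.
#' @return Data frame with `key` and logical tag columns `clinvar_consensus`,
#'   `adjudicated`, `nmd_positive`; one row per distinct variant.
#' @export
assemble_pathogenic_set <- function(calls, adjudications = NULL, nmd = NULL,
                                    lof_mechanism_genes = character(0)) {
  tags <- list()
  add <- function(keys, tag) {
    for (k in keys) {
      cur <- tags[[k]] %||% character(0)
      tags[[k]] <<- union(cur, tag)
    }
  }
  if (!is.null(calls) && nrow(calls) > 0L)
    add(calls$key[calls$status == "consensus_pathogenic"], "clinvar_consensus")
  if (!is.null(adjudications) && nrow(adjudications) > 0L) {
    ak <- variant_key(adjudications$chrom, adjudications$pos,
                      adjudications$ref, adjudications$alt)
    path <- adjudications$classification %in% c("P", "LP")
    if (!is.null(calls)) {
      at_consensus <- ak %in% calls$key[calls$status %in%
                                          c("consensus_pathogenic", "consensus_benign")]
      if (any(at_consensus)) {
        warning(sum(at_consensus), " adjudication(s) for variants already at ",
                "consensus ignored; consensus wins")
        path <- path & !at_consensus
      }
    }
    add(ak[path], "adjudicated")
  }
  if (!is.null(nmd) && nrow(nmd) > 0L) {
    nk <- variant_key(nmd$chrom, nmd$pos, nmd$ref, nmd$alt)
    sel <- nmd$nmd_status == "NMD_positive" & nmd$gene %in% lof_mechanism_genes
    add(nk[sel], "nmd_positive")
  }
  keys <- names(tags)
  data.frame(
    key = keys,
    clinvar_consensus = vapply(tags, function(t) "clinvar_consensus" %in% t, logical(1)),
    adjudicated = vapply(tags, function(t) "adjudicated" %in% t, logical(1)),
    nmd_positive = vapply(tags, function(t) "nmd_positive" %in% t, logical(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
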