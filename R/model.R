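#' A query or reference protein chain
#'
#' Carries the full deposited (SEQRES) sequence together with the
#' observed-residue ranges — the subset of positions actually resolved
#' in the structure's ATOM records — plus entry-level metadata used by
#' the confidence gate.
#'
#' @param pdb_id 4-character entry code.
#' @param chain_id chain identifier.
#' @param seqres amino-acid string (one-letter codes).
#' @param observed_ranges `residue_ranges` in SEQRES index space;
#'   sorted, non-overlapping, within `[1, nchar(seqres)]`.
#' @param resolution resolution in Angstroms, or `NA` for
#'   non-crystallographic entries.
#' @param description entry title / compound text.
#' @return A `chain_record` list.
#' @export
chain_record <- function(pdb_id, chain_id, seqres,
                         observed_ranges = residue_ranges(1L, nchar(seqres)),
                         resolution = NA_real_, description = "") {
  stopifnot(nchar(pdb_id) == 4L, nzchar(chain_id), nchar(seqres) >= 1L)
  observed_ranges <- normalize_ranges(observed_ranges)
  if (nrow(observed_ranges) > 0L &&
      (min(observed_ranges$start) < 1L ||
       max(observed_ranges$end) > nchar(seqres))) {
    stop("observed ranges outside [1, len(seqres)]", call. = FALSE)
  }
  structure(list(pdb_id = pdb_id, chain_id = chain_id, seqres = seqres,
                 observed_ranges = observed_ranges,
                 resolution = as.numeric(resolution),
                 description = as.character(description)),
            class = "chain_record")
}

chain_key <- function(pdb_id, chain_id) paste0(pdb_id, chain_id)

#' @export
print.chain_record <- function(x, ...) {
  cat(sprintf("<chain %s%s> %d residues, observed %s\n", x$pdb_id, x$chain_id,
              nchar(x$seqres), format_ranges(x$observed_ranges)))
  invisible(x)
}

#' A classified domain definition
#'
#' @param sid 7-character stable domain identifier.
#' @param sunid sunid of the domain-level hierarchy node.
#' @param pdb_id 4-character entry code.
#' @param segments data.frame with columns `chain_id`, `start`, `end`
#'   (SEQRES indices), sorted and non-overlapping per chain. A domain
#'   whose segments span more than one chain is a "genetic domain".
#' @param sequence SEQRES-based amino-acid sequence concatenated over
#'   the segments, in segment order.
#' @return A `domain_definition` list with an `is_genetic` flag.
#' @export
domain_definition <- function(sid, sunid, pdb_id, segments, sequence) {
  stopifnot(is.data.frame(segments), nrow(segments) >= 1L,
            all(c("chain_id", "start", "end") %in% names(segments)))
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  if (any(segments$end < segments$start)) {
    stop("domain segment with end < start", call. = FALSE)
  }
  total <- sum(segments$end - segments$start + 1L)
  if (total != nchar(sequence)) {
    stop(sprintf("domain %s: sequence length %d != total range length %d",
                 sid, nchar(sequence), total), call. = FALSE)
  }
  structure(list(sid = sid, sunid = as.integer(sunid), pdb_id = pdb_id,
                 segments = segments,
                 is_genetic = length(unique(segments$chain_id)) > 1L,
                 sequence = sequence),
            class = "domain_definition")
}

domain_ranges <- function(domain) {
  residue_ranges(domain$segments$start, domain$segments$end)
}

#' Pipeline thresholds
#'
#' All residue thresholds default to 10 and the E-value threshold to
#' 1e-4: hits must be at least as significant as 1e-4 and cover the
#' target domain to within 10 residues of each end; boundary extension
#' reaches at most 10 residues to a chain terminus or ATOM-record gap;
#' an unassigned observed region longer than 10 residues blocks the
#' high-confidence gate; benchmark boundaries may deviate by at most 10
#' residues; and entries at 3 Angstrom resolution or worse are gated out.
#'
#' @param e_max E-value threshold (inclusive).
#' @param target_end_slack residues a hit may miss from each target end.
#' @param extension_limit maximum boundary extension, residues.
#' @param unassigned_limit longest tolerated unassigned observed region.
#' @param benchmark_tolerance residues of allowed boundary deviation.
#' @param resolution_cutoff Angstroms; resolution >= cutoff is gated out.
#' @param protein_identity,family_identity percent-identity thresholds
#'   for inheriting the target's protein / family node (species always
#'   requires 100).
#' @param exclusion_keywords entry-description substrings (case
#'   insensitive) marking ribosomal or synthetic entries.
#' @return A `scop_params` list.
#' @export
default_params <- function(e_max = 1e-4, target_end_slack = 10L,
                           extension_limit = 10L, unassigned_limit = 10L,
                           benchmark_tolerance = 10L, resolution_cutoff = 3.0,
                           protein_identity = 90, family_identity = 70,
                           exclusion_keywords = c("ribosom", "synthetic construct")) {
  p <- list(e_max = e_max, target_end_slack = as.integer(target_end_slack),
            extension_limit = as.integer(extension_limit),
            unassigned_limit = as.integer(unassigned_limit),
            benchmark_tolerance = as.integer(benchmark_tolerance),
            resolution_cutoff = resolution_cutoff,
            protein_identity = protein_identity,
            family_identity = family_identity,
            exclusion_keywords = exclusion_keywords)
  num <- c("e_max", "target_end_slack", "extension_limit", "unassigned_limit",
           "benchmark_tolerance", "resolution_cutoff")
  if (any(vapply(p[num], function(v) v <= 0, TRUE))) {
    stop("all thresholds must be > 0", call. = FALSE)
  }
  structure(p, class = "scop_params")
}

#' A classified release: hierarchy, domains, chains
#'
#' @param hierarchy a `scop_hierarchy` data.frame.
#' @param domains list of [domain_definition()] objects.
#' @param chains list of [chain_record()] objects.
#' @param version_label release label string.
#' @return A `release_bundle` list; consistency is checked (every
#'   domain's sunid must be a domain-level hierarchy node, every
#'   non-genetic domain's chain must exist).
#' @export
release_bundle <- function(hierarchy, domains = list(), chains = list(),
                           version_label = "0.0") {
  names(domains) <- vapply(domains, `[[`, "", "sid")
  names(chains) <- vapply(chains, function(ch) chain_key(ch$pdb_id, ch$chain_id), "")
  if (anyDuplicated(names(chains))) stop("duplicate chain key", call. = FALSE)
  b <- structure(list(hierarchy = hierarchy, domains = domains,
                      chains = chains, version_label = version_label),
                 class = "release_bundle")
  validate_bundle(b)
  b
}

validate_bundle <- function(bundle) {
  validate_hierarchy(bundle$hierarchy)
  h <- bundle$hierarchy
  for (d in bundle$domains) {
    i <- match(d$sunid, h$sunid)
    if (is.na(i) || h$level[i] != "domain") {
      stop(sprintf("domain %s: sunid %d is not a domain-level node",
                   d$sid, d$sunid), call. = FALSE)
    }
    if (!identical(h$sid[i], d$sid)) {
      stop(sprintf("domain %s: sid mismatch with hierarchy node %d",
                   d$sid, d$sunid), call. = FALSE)
    }
    for (ck in chain_key(d$pdb_id, unique(d$segments$chain_id))) {
      if (!ck %in% names(bundle$chains)) {
        stop(sprintf("domain %s references unknown chain %s", d$sid, ck),
             call. = FALSE)
      }
    }
  }
  invisible(bundle)
}

#' @export
print.release_bundle <- function(x, ...) {
  cat(sprintf("<release %s> %d hierarchy nodes, %d domains, %d chains\n",
              x$version_label, nrow(x$hierarchy), length(x$domains),
              length(x$chains)))
  invisible(x)
}
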