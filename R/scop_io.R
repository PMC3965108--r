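#' @importFrom Biostrings readAAStringSet
NULL

# Parseable-file dialects (pinned for byte-exact round trips):
#   dir.des: sunid <TAB> level-code <TAB> sccs <TAB> sid <TAB> description
#            level codes cl,cf,sf,fa,dm,sp,px; "-" for absent sccs/sid
#   dir.hie: sunid <TAB> parent_sunid <TAB> comma-list of children ("-" roots/leaves)
#   dir.cla: sid <TAB> pdb_id <TAB> region <TAB> sccs <TAB> sunid <TAB>
#            cl=..,cf=..,sf=..,fa=..,dm=..,sp=..,px=..
#   region:  "chain:start-end" segments joined by ","; whole chain "chain:";
#            chainless "-". SEQRES indices (no author numbering/insertion codes).
# All files UTF-8, LF, first line "# <name> <version_label>".

na_dash <- function(x) ifelse(is.na(x) | !nzchar(x), "-", x)
dash_na <- function(x) ifelse(x == "-", NA_character_, x)

#' Region string of a domain
#'
#' `chain:start-end` segments joined by commas; a segment covering a
#' chain's full SEQRES is abbreviated to `chain:`.
#'
#' @param domain a [domain_definition()].
#' @param chains named list of [chain_record()]s (keys `pdb_id+chain_id`),
#'   used to detect whole-chain segments.
#' @return Character scalar.
#' @export
region_string <- function(domain, chains = list()) {
  seg <- domain$segments
  out <- character(nrow(seg))
  for (i in seq_len(nrow(seg))) {
    ck <- chain_key(domain$pdb_id, seg$chain_id[i])
    len <- if (ck %in% names(chains)) nchar(chains[[ck]]$seqres) else NA_integer_
    if (!is.na(len) && seg$start[i] == 1L && seg$end[i] == len) {
      out[i] <- sprintf("%s:", seg$chain_id[i])
    } else {
      out[i] <- sprintf("%s:%d-%d", seg$chain_id[i], seg$start[i], seg$end[i])
    }
  }
  paste(out, collapse = ",")
}

#' Parse a region string into domain segments
#' @param region region string (see [region_string()]).
#' @param pdb_id entry code the region belongs to.
#' @param chains named list of [chain_record()]s, needed to expand
#'   whole-chain (`chain:`) segments.
#' @return data.frame with columns `chain_id`, `start`, `end`.
#' @export
parse_region_string <- function(region, pdb_id, chains = list()) {
  if (region == "-") stop("chainless regions are not supported", call. = FALSE)
  parts <- strsplit(region, ",", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^([^:]+):(?:([0-9]+)-([0-9]+))?$", parts))
  seg <- lapply(seq_along(parts), function(i) {
    g <- m[[i]]
    if (length(g) == 0L || !nzchar(g[1L])) {
      stop(sprintf("malformed region segment '%s'", parts[i]), call. = FALSE)
    }
    if (nzchar(g[2L]) && !nzchar(g[3L])) {  # "chain:" whole-chain form
      ck <- chain_key(pdb_id, g[2L])
      if (!ck %in% names(chains)) {
        stop(sprintf("whole-chain region '%s' needs chain %s", parts[i], ck),
             call. = FALSE)
      }
      data.frame(chain_id = g[2L], start = 1L,
                 end = nchar(chains[[ck]]$seqres))
    } else {
      data.frame(chain_id = g[2L], start = as.integer(g[3L]),
                 end = as.integer(g[4L]))
    }
  })
  do.call(rbind, seg)
}

wrap_seq <- function(s, width = 60L) {
  if (nchar(s) == 0L) return(character())
  starts <- seq.int(1L, nchar(s), by = width)
  substring(s, starts, pmin(starts + width - 1L, nchar(s)))
}

#' Domain sequences as FASTA text
#'
#' One record per non-genetic domain, header
#' `>sid pdb_id region (sccs)`, sequence wrapped at 60 columns. Genetic
#' (multi-chain) domains are excluded from this searchable set; write
#' them separately via `genetic = TRUE`. Empty-sequence domains are
#' skipped with a warning.
#'
#' @param bundle a [release_bundle()].
#' @param genetic if `TRUE`, emit only genetic domains instead.
#' @return Character scalar of FASTA text ("" when no records).
#' @export
write_domain_fasta <- function(bundle, genetic = FALSE) {
  doms <- bundle$domains[order(names(bundle$domains))]
  out <- character()
  h <- bundle$hierarchy
  for (d in doms) {
    if (d$is_genetic != genetic) next
    if (nchar(d$sequence) == 0L) {
      warning(sprintf("domain %s has empty sequence; skipped", d$sid))
      next
    }
    sccs <- h$sccs[match(d$sunid, h$sunid)]
    hdr <- sprintf(">%s %s %s (%s)", d$sid, d$pdb_id,
                   region_string(d, bundle$chains), na_dash(sccs))
    out <- c(out, hdr, wrap_seq(d$sequence))
  }
  if (length(out) == 0L) return("")
  paste0(paste(out, collapse = "\n"), "\n")
}

write_chain_fasta <- function(bundle) {
  chs <- bundle$chains[order(names(bundle$chains))]
  out <- character()
  for (ch in chs) {
    hdr <- sprintf(">%s%s observed=%s resolution=%s %s",
                   ch$pdb_id, ch$chain_id,
                   na_dash(format_ranges(ch$observed_ranges)),
                   ifelse(is.na(ch$resolution), "NA",
                          sprintf("%.2f", ch$resolution)),
                   ch$description)
    out <- c(out, sub(" +$", "", hdr), wrap_seq(ch$seqres))
  }
  if (length(out) == 0L) return("")
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Write a release as SCOP-compatible parseable files
#'
#' Emits `dir.des`, `dir.hie`, `dir.cla`, the searchable domain FASTA
#' (`domains.fa`), an auxiliary FASTA of genetic domains
#' (`genetic_domains.fa`) and the chain FASTA (`chains.fa`). Output
#' ordering is deterministic (by sunid / sid / chain key), so the bytes
#' are independent of in-memory insertion order.
#'
#' @param bundle a consistent [release_bundle()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the named character vector of file paths.
#' @export
write_release <- function(bundle, out_dir) {
  validate_bundle(bundle)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- bundle$hierarchy[order(bundle$hierarchy$sunid), , drop = FALSE]
  v <- bundle$version_label

  des <- c(sprintf("# dir.des %s", v),
           sprintf("%d\t%s\t%s\t%s\t%s", h$sunid, level_codes[h$level],
                   na_dash(h$sccs), na_dash(h$sid), h$description))

  kids <- vapply(h$sunid, function(s) {
    ch <- hierarchy_children(h, s)
    if (length(ch) == 0L) "-" else paste(ch, collapse = ",")
  }, "")
  hie <- c(sprintf("# dir.hie %s", v),
           sprintf("%d\t%s\t%s", h$sunid,
                   ifelse(is.na(h$parent_sunid), "-", h$parent_sunid), kids))

  doms <- bundle$domains[order(names(bundle$domains))]
  cla <- sprintf("# dir.cla %s", v)
  for (d in doms) {
    anc <- vapply(scop_levels(), function(lv) get_ancestor(h, d$sunid, lv), 1L)
    lineage <- paste(sprintf("%s=%d", level_codes[scop_levels()], anc),
                     collapse = ",")
    sccs <- h$sccs[match(d$sunid, h$sunid)]
    cla <- c(cla, sprintf("%s\t%s\t%s\t%s\t%d\t%s", d$sid, d$pdb_id,
                          region_string(d, bundle$chains), na_dash(sccs),
                          d$sunid, lineage))
  }

  paths <- c(des = file.path(out_dir, "dir.des"),
             hie = file.path(out_dir, "dir.hie"),
             cla = file.path(out_dir, "dir.cla"),
             domains = file.path(out_dir, "domains.fa"),
             genetic = file.path(out_dir, "genetic_domains.fa"),
             chains = file.path(out_dir, "chains.fa"))
  write_lf <- function(lines, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  }
  write_lf(des, paths["des"])
  write_lf(hie, paths["hie"])
  write_lf(cla, paths["cla"])
  cat(write_domain_fasta(bundle, genetic = FALSE), file = paths["domains"])
  cat(write_domain_fasta(bundle, genetic = TRUE), file = paths["genetic"])
  cat(write_chain_fasta(bundle), file = paths["chains"])
  invisible(paths)
}

read_tsv_body <- function(path, n_fields, what) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L || !startsWith(lines[1L], "# ")) {
    stop(sprintf("%s: missing header line", path), call. = FALSE)
  }
  version <- sub(sprintf("^# %s ?", what), "", lines[1L])
  body <- lines[-1L]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) != n_fields)
  if (length(bad) > 0L) {
    stop(sprintf("%s line %d: expected %d tab-separated fields",
                 path, bad[1L] + 1L, n_fields), call. = FALSE)
  }
  list(version = version, fields = fields)
}

parse_chain_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  chains <- list()
  for (i in seq_along(seqs)) {
    hdr <- names(seqs)[i]
    toks <- strsplit(hdr, " ", fixed = TRUE)[[1L]]
    key <- toks[1L]
    obs <- sub("^observed=", "", toks[grepl("^observed=", toks)][1L])
    res <- sub("^resolution=", "", toks[grepl("^resolution=", toks)][1L])
    desc_toks <- toks[-(1:3)]
    pdb_id <- substr(key, 1L, 4L)
    cid <- substr(key, 5L, nchar(key))
    s <- as.character(seqs[[i]])
    chains[[key]] <- chain_record(
      pdb_id, cid, s,
      observed_ranges = if (obs == "-") residue_ranges() else parse_ranges(obs),
      resolution = if (res == "NA") NA_real_ else as.numeric(res),
      description = paste(desc_toks, collapse = " "))
  }
  chains
}

#' Read a release from SCOP-compatible parseable files
#'
#' @param des_path,hie_path,cla_path paths to `dir.des`, `dir.hie`,
#'   `dir.cla` (dialects documented in [write_release()]).
#' @param fasta_paths named list/vector with elements `domains`,
#'   `chains` and optionally `genetic`, pointing at the FASTA files.
#' @return A consistent [release_bundle()]. Malformed lines raise parse
#'   errors naming file and line; dangling sunid references raise
#'   integrity errors.
#' @export
read_release <- function(des_path, hie_path, cla_path, fasta_paths) {
  des <- read_tsv_body(des_path, 5L, "dir.des")
  hie <- read_tsv_body(hie_path, 3L, "dir.hie")
  cla <- read_tsv_body(cla_path, 6L, "dir.cla")

  f <- function(fields, k) vapply(fields, `[[`, "", k)
  code2level <- stats::setNames(names(level_codes), level_codes)
  des_sunid <- as.integer(f(des$fields, 1L))
  lv_codes <- f(des$fields, 2L)
  bad <- which(!lv_codes %in% level_codes)
  if (length(bad) > 0L) {
    stop(sprintf("%s line %d: unknown level code '%s'", des_path,
                 bad[1L] + 1L, lv_codes[bad[1L]]), call. = FALSE)
  }

  parent_raw <- f(hie$fields, 2L)
  hie_sunid <- as.integer(f(hie$fields, 1L))
  parent <- rep(NA_integer_, length(parent_raw))
  parent[parent_raw != "-"] <- as.integer(parent_raw[parent_raw != "-"])
  pm <- match(des_sunid, hie_sunid)
  if (anyNA(pm)) {
    stop(sprintf("%s: sunid %d has no dir.hie record", hie_path,
                 des_sunid[which(is.na(pm))[1L]]), call. = FALSE)
  }
  dangling <- which(!is.na(parent) & !parent %in% des_sunid)
  if (length(dangling) > 0L) {
    stop(sprintf("%s line %d: parent sunid %d not in dir.des", hie_path,
                 dangling[1L] + 1L, parent[dangling[1L]]), call. = FALSE)
  }

  hierarchy <- hierarchy_table(
    sunid = des_sunid,
    level = unname(code2level[lv_codes]),
    sccs = dash_na(f(des$fields, 3L)),
    sid = dash_na(f(des$fields, 4L)),
    parent_sunid = parent[pm],
    description = f(des$fields, 5L))

  chains <- parse_chain_fasta(fasta_paths[["chains"]])

  dom_seqs <- Biostrings::readAAStringSet(fasta_paths[["domains"]])
  gpath <- fasta_paths[["genetic"]]
  if (!is.null(gpath) && file.exists(gpath) && file.size(gpath) > 0L) {
    dom_seqs <- c(dom_seqs, Biostrings::readAAStringSet(gpath))
  }
  seq_by_sid <- stats::setNames(as.character(dom_seqs),
                                sub(" .*$", "", names(dom_seqs)))

  domains <- list()
  for (i in seq_along(cla$fields)) {
    g <- cla$fields[[i]]
    sunid <- as.integer(g[5L])
    j <- match(sunid, hierarchy$sunid)
    if (is.na(j)) {
      stop(sprintf("%s line %d: sunid %d not in hierarchy", cla_path, i + 1L,
                   sunid), call. = FALSE)
    }
    if (hierarchy$level[j] != "domain") {
      stop(sprintf("%s line %d: sunid %d is not domain-level", cla_path,
                   i + 1L, sunid), call. = FALSE)
    }
    sid <- g[1L]
    if (!sid %in% names(seq_by_sid)) {
      stop(sprintf("%s line %d: no FASTA sequence for %s", cla_path, i + 1L,
                   sid), call. = FALSE)
    }
    segments <- parse_region_string(g[3L], g[2L], chains)
    domains[[sid]] <- domain_definition(sid, sunid, g[2L], segments,
                                        seq_by_sid[[sid]])
  }

  release_bundle(hierarchy, domains, chains, version_label = des$version)
}
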