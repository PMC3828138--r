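#' Microsatellite signature datasets
#'
#' An `ms_dataset` holds the repeat-count signatures of a set of single
#' cells over a panel of microsatellite (MS) alleles, together with cell
#' metadata, the panel description, and (optionally) a root signature for
#' the putative zygote.
#'
#' Internally signatures are stored as an integer matrix with one row per
#' cell (rownames = sample ids) and one column per *allele key*.  An allele
#' key identifies a (locus, allele index) pair and is written
#' `"<locus>|<index>"`; autosomal loci contribute two keys, chromosome-X
#' loci in males contribute one.  Missing measurements are `NA`.
#'
#' @param signatures integer matrix, cells x allele keys, `NA` = missing.
#' @param cells data.frame with columns `sample_id`, `individual_id`,
#'   `cell_type` (one row per signature row).
#' @param panel data.frame describing the panel, one row per allele key,
#'   with columns `allele_key`, `locus`, `allele_index`, `unit_length`
#'   (basic repeat unit in bp, 1 or 2) and `ref_repeats` (reference repeat
#'   number, may be `NA`).
#' @param root optional named numeric vector over the allele keys: the
#'   root (putative zygote) signature.
#' @param provenance character vector of source file names.
#'
#' @return An object of class `ms_dataset`.
#' @export
ms_dataset <- function(signatures, cells, panel, root = NULL,
                       provenance = character()) {
  stopifnot(is.matrix(signatures), nrow(signatures) == nrow(cells))
  if (anyDuplicated(cells$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(cells$sample_id[duplicated(cells$sample_id)]),
               collapse = ", "))
  rownames(signatures) <- cells$sample_id
  if (!all(colnames(signatures) %in% panel$allele_key))
    stop("panel does not cover all allele keys in the signatures")
  bad <- !is.na(signatures) & signatures < 1
  if (any(bad))
    stop("repeat counts must be >= 1 for non-missing alleles")
  structure(
    list(signatures = signatures, cells = cells,
         panel = panel[match(colnames(signatures), panel$allele_key), ,
                       drop = FALSE],
         root = root, provenance = provenance),
    class = "ms_dataset")
}

#' @export
print.ms_dataset <- function(x, ...) {
  cat("ms_dataset:", nrow(x$signatures), "cells,",
      length(unique(x$panel$locus)), "loci (",
      ncol(x$signatures), "alleles )\n")
  cat("  individuals:",
      paste(unique(x$cells$individual_id), collapse = ", "), "\n")
  cat("  root signature:", if (is.null(x$root)) "none" else
    paste0("present (", attr(x$root, "policy"), ")"), "\n")
  invisible(x)
}

#' Number of cells in a dataset
#' @param dataset an `ms_dataset`.
#' @return integer.
#' @export
n_cells <- function(dataset) nrow(dataset$signatures)

#' Per-cell count of valid (non-missing) alleles
#' @param dataset an `ms_dataset`.
#' @return named integer vector.
#' @export
n_valid_alleles <- function(dataset) rowSums(!is.na(dataset$signatures))

## Parse a locus name of the panel convention
## [Organism][Chromosome]_[Unit][repeats]_[serial], e.g. "MX_Mono27_12".
## Unknown patterns fall back to unit length 1 and NA reference repeats.
parse_locus_name <- function(locus) {
  unit <- rep(1L, length(locus))
  unit[grepl("_Di", locus, ignore.case = TRUE)] <- 2L
  refm <- regmatches(locus, regexpr("(Mono|Di)[0-9]+", locus,
                                    ignore.case = TRUE))
  ref <- rep(NA_integer_, length(locus))
  has <- grepl("(Mono|Di)[0-9]+", locus, ignore.case = TRUE)
  ref[has] <- as.integer(gsub("[^0-9]", "", refm))
  chrom_x <- grepl("^.X_", locus)
  data.frame(locus = locus, unit_length = unit, ref_repeats = ref,
             chrom_x = chrom_x, stringsAsFactors = FALSE)
}

#' Read a single-cell MS allele-length table
#'
#' Reads a delimited table in the supplementary layout: a header row of
#' locus names, then one row per cell with `Sample ID`, `Animal ID`,
#' `Tissue` followed by two columns per locus holding the two alleles'
#' repeat counts.  `"X"` marks a missing measurement and an empty cell a
#' locus that was not measured; both become `NA`.
#'
#' Heterozygous autosomal alleles are stored sorted in increasing order
#' within each cell (the table layout does not encode phase).  An
#' autosomal locus for which a cell has exactly one non-missing allele is
#' treated as an allelic dropout and both alleles are set missing for that
#' cell; loci flagged as chromosome X (single-allele) are exempt.
#'
#' @param path path to a tab- or comma-delimited table.
#' @param metadata_path optional path to a metadata table with columns
#'   `Animal ID`, and optionally `Gender`, `Age`, `Species`; joined on
#'   animal id.
#' @param panel optional panel data.frame as in [ms_dataset()]; by default
#'   it is derived from the locus names.
#' @param dropout_exclusion apply the allelic-dropout rule above
#'   (default `TRUE`).
#' @param sep field separator; guessed from the file when `NULL`.
#' @return An [ms_dataset()].
#' @export
read_allele_table <- function(path, metadata_path = NULL, panel = NULL,
                              dropout_exclusion = TRUE, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, fill = TRUE,
                           quote = "\"")
  header <- as.character(unlist(raw[1L, ]))
  body <- raw[-1L, , drop = FALSE]
  id_cols <- 3L
  n_allele_cols <- ncol(raw) - id_cols
  if (n_allele_cols < 2L || n_allele_cols %% 2L != 0L)
    stop("expected two columns per locus after Sample ID/Animal ID/Tissue")
  locus_names <- header[seq(id_cols + 1L, ncol(raw), by = 2L)]
  locus_names <- trimws(locus_names)
  if (any(locus_names == ""))
    stop("empty locus name in header")
  cells <- data.frame(sample_id = trimws(body[[1L]]),
                      individual_id = trimws(body[[2L]]),
                      cell_type = trimws(body[[3L]]),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(cells$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(cells$sample_id[duplicated(cells$sample_id)]),
               collapse = ", "))

  vals <- as.matrix(body[, -(1:id_cols), drop = FALSE])
  vals <- trimws(vals)
  vals[vals %in% c("", "X", "x", "NA")] <- NA
  bad <- !is.na(vals) & !grepl("^-?[0-9]+$", vals)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer repeat value '%s' at row %s (sample %s), %s",
                 vals[bad][1L], w[1L], cells$sample_id[w[1L]],
                 sprintf("locus %s", locus_names[ceiling(w[2L] / 2)])))
  }
  num <- matrix(as.integer(vals), nrow = nrow(vals))

  if (is.null(panel)) {
    info <- parse_locus_name(locus_names)
  } else {
    info <- panel[match(locus_names, panel$locus), , drop = FALSE]
    if (anyNA(info$locus))
      stop("unknown locus in data vs. panel: ",
           paste(locus_names[is.na(info$locus)], collapse = ", "))
    if (is.null(info$chrom_x)) info$chrom_x <- FALSE
  }

  n_loci <- length(locus_names)
  for (l in seq_len(n_loci)) {
    c1 <- 2L * l - 1L; c2 <- 2L * l
    a <- num[, c1]; b <- num[, c2]
    ## sort the two alleles within each cell (layout encodes no phase)
    lo <- pmin(a, b); hi <- pmax(a, b)
    one <- xor(is.na(a), is.na(b))
    lo[one] <- ifelse(is.na(a[one]), b[one], a[one])
    hi[one] <- NA_integer_
    if (dropout_exclusion && !isTRUE(info$chrom_x[l])) {
      ## exactly one allele measured on an autosomal locus -> dropout
      lo[one] <- NA
    }
    num[, c1] <- lo; num[, c2] <- hi
  }

  keys <- as.vector(rbind(paste0(locus_names, "|1"),
                          paste0(locus_names, "|2")))
  colnames(num) <- keys
  ## chromosome-X loci carry a single allele key
  drop_keys <- paste0(info$locus[info$chrom_x], "|2")
  num <- num[, !(colnames(num) %in% drop_keys), drop = FALSE]

  panel_df <- data.frame(
    allele_key = colnames(num),
    locus = sub("\\|[12]$", "", colnames(num)),
    allele_index = as.integer(sub("^.*\\|", "", colnames(num))),
    stringsAsFactors = FALSE)
  panel_df$unit_length <- info$unit_length[match(panel_df$locus, info$locus)]
  panel_df$ref_repeats <- info$ref_repeats[match(panel_df$locus, info$locus)]

  if (!is.null(metadata_path)) {
    md <- utils::read.table(metadata_path, sep = sep, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "\"")
    names(md) <- tolower(gsub("[ _]", "", names(md)))
    j <- match(cells$individual_id, md$animalid)
    for (field in c("gender", "age", "species"))
      if (!is.null(md[[field]])) cells[[field]] <- md[[field]][j]
  }

  ms_dataset(num, cells, panel_df,
             provenance = c(path, metadata_path))
}

#' Write a dataset back in the two-columns-per-locus layout
#'
#' Inverse of [read_allele_table()]: tab-delimited, header of locus names,
#' `X` for missing values.  Chromosome-X single-allele loci are written
#' with an empty second column.
#'
#' @param dataset an [ms_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_allele_table <- function(dataset, path) {
  loci <- unique(dataset$panel$locus)
  header <- c("Sample ID", "Animal ID", "Tissue",
              as.vector(rbind(loci, "")))
  rows <- lapply(seq_len(n_cells(dataset)), function(i) {
    vals <- unlist(lapply(loci, function(l) {
      k1 <- paste0(l, "|1"); k2 <- paste0(l, "|2")
      v1 <- if (k1 %in% colnames(dataset$signatures))
        dataset$signatures[i, k1] else NA
      v2 <- if (k2 %in% colnames(dataset$signatures))
        dataset$signatures[i, k2] else NA
      c(if (is.na(v1)) "X" else as.character(v1),
        if (k2 %in% colnames(dataset$signatures)) {
          if (is.na(v2)) "X" else as.character(v2)
        } else "")
    }))
    c(dataset$cells$sample_id[i], dataset$cells$individual_id[i],
      dataset$cells$cell_type[i], vals)
  })
  lines <- vapply(c(list(header), rows), paste, "", collapse = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Root (putative zygote) signature of a dataset
#'
#' Builds the reference signature used as the tree root/outgroup.  Three
#' policies are supported: `tail_sample` takes the signature of a
#' designated bulk sample verbatim (the convention for mice, where tail
#' DNA stands in for the zygote); `median_of_cells` takes the per-allele
#' median over all cells (the convention for humans), using the lower
#' median for even counts so root values stay integral; `weighted_mean`
#' combines several per-organism zygote signatures, by default weighting
#' each organism by its cell count (the convention for multi-individual
#' trees).
#'
#' @param dataset an [ms_dataset()].
#' @param policy `"tail_sample"`, `"median_of_cells"` or `"weighted_mean"`.
#' @param tail_sample_id sample id of the tail/bulk sample
#'   (`tail_sample` policy).
#' @param zygotes list of named numeric root signatures (`weighted_mean`).
#' @param weights optional numeric weights for `zygotes`; defaults to the
#'   organisms' cell counts when the zygotes are named by individual id,
#'   else to equal weights.
#' @return named numeric vector over the allele keys, class `ms_root`,
#'   with the policy stored as an attribute.
#' @export
compute_root_signature <- function(dataset,
                                   policy = c("median_of_cells",
                                              "tail_sample",
                                              "weighted_mean"),
                                   tail_sample_id = NULL,
                                   zygotes = NULL, weights = NULL) {
  policy <- match.arg(policy)
  if (n_cells(dataset) == 0L) stop("empty dataset")
  sig <- dataset$signatures
  root <- switch(policy,
    tail_sample = {
      if (is.null(tail_sample_id) ||
          !tail_sample_id %in% rownames(sig))
        stop("tail sample not found: ", tail_sample_id)
      r <- sig[tail_sample_id, ]
      miss <- is.na(r)
      if (any(miss)) {
        fill <- apply(sig[, miss, drop = FALSE], 2L, lower_median)
        dead <- is.na(fill)
        if (any(dead))
          warning("dropping alleles absent from the tail sample and all ",
                  "cells: ", paste(names(fill)[dead], collapse = ", "))
        r[miss] <- fill
        r <- r[!is.na(r)]
      }
      r
    },
    median_of_cells = {
      r <- apply(sig, 2L, lower_median)
      r[!is.na(r)]
    },
    weighted_mean = {
      if (is.null(zygotes) || length(zygotes) == 0L)
        stop("weighted_mean policy needs at least one zygote signature")
      if (is.null(weights)) {
        ids <- names(zygotes)
        weights <- if (!is.null(ids) &&
                       all(ids %in% dataset$cells$individual_id)) {
          as.numeric(table(dataset$cells$individual_id)[ids])
        } else rep(1, length(zygotes))
      }
      keys <- Reduce(intersect, lapply(zygotes, names))
      m <- do.call(rbind, lapply(zygotes, function(z) z[keys]))
      r <- as.numeric(crossprod(weights, m)) / sum(weights)
      names(r) <- keys
      r
    })
  structure(root, policy = policy, class = c("ms_root", "numeric"))
}

## lower median of the non-missing values; NA when all missing
lower_median <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0L) return(NA_real_)
  x[[floor((n + 1) / 2)]]
}

#' Alleles measured in both of two cells
#'
#' Returns the allele keys that are non-missing in both signatures.  The
#' pair is flagged unreliable (attribute `reliable = FALSE`) when fewer
#' than `min_shared` alleles remain.  For heterozygous autosomal loci the
#' two alleles are matched by sorted value within each cell; when, in
#' either cell, the two alleles differ by less than `min_allele_sep`
#' repeat units (but are not equal) the assignment is ambiguous and the
#' locus is dropped for that pair.
#'
#' @param dataset an [ms_dataset()].
#' @param i,j sample ids or row indices of the two cells.
#' @param min_shared minimum number of shared alleles below which the pair
#'   is flagged unreliable (default 25).
#' @param min_allele_sep minimum repeat difference for a heterozygous
#'   autosomal locus to be considered phase-resolvable (default 2).
#' @return character vector of allele keys with attribute `reliable`.
#' @export
shared_valid_alleles <- function(dataset, i, j, min_shared = 25L,
                                 min_allele_sep = 2L) {
  si <- dataset$signatures[i, ]
  sj <- dataset$signatures[j, ]
  ok <- !is.na(si) & !is.na(sj)
  ## ambiguous heterozygous autosomal loci: drop per pair
  two <- dataset$panel$locus[dataset$panel$allele_index == 2L]
  if (length(two)) {
    k1 <- paste0(two, "|1"); k2 <- paste0(two, "|2")
    amb <- function(s) {
      d <- abs(s[k1] - s[k2])
      !is.na(d) & d > 0 & d < min_allele_sep
    }
    drop <- amb(si) | amb(sj)
    drop[is.na(drop)] <- FALSE
    if (any(drop)) {
      bad_keys <- c(k1[drop], k2[drop])
      ok[names(ok) %in% bad_keys] <- FALSE
    }
  }
  keys <- names(ok)[ok]
  if (length(keys) == 0L)
    stop("no shared valid alleles between ", i, " and ", j,
         ": distance undefined")
  structure(keys, reliable = length(keys) >= min_shared)
}
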