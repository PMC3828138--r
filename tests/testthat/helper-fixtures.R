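# Shared fixtures: tiny datasets and trees built in code.

# dataset with explicit repeat matrix; one allele per locus
make_dataset <- function(sig, individuals = NULL, types = NULL,
                         root = NULL, unit = NULL) {
  loci <- sprintf("L%02d", seq_len(ncol(sig)))
  colnames(sig) <- paste0(loci, "|1")
  n <- nrow(sig)
  if (is.null(rownames(sig))) rownames(sig) <- sprintf("c%d", seq_len(n))
  cells <- data.frame(
    sample_id = rownames(sig),
    individual_id = if (is.null(individuals)) rep("I1", n) else individuals,
    cell_type = if (is.null(types)) rep("T1", n) else types,
    stringsAsFactors = FALSE)
  panel <- data.frame(allele_key = colnames(sig), locus = loci,
                      allele_index = 1L,
                      unit_length = if (is.null(unit))
                        rep(1L, ncol(sig)) else unit,
                      ref_repeats = NA_integer_,
                      stringsAsFactors = FALSE)
  if (!is.null(root)) {
    root <- structure(as.numeric(root), names = colnames(sig),
                      policy = "fixture",
                      class = c("ms_root", "numeric"))
  }
  ms_dataset(sig, cells, panel, root = root)
}

# S4-layout table text for read_allele_table (two columns per locus)
write_s4_fixture <- function(path, rows, loci) {
  header <- paste(c("Sample ID", "Animal ID", "Tissue",
                    as.vector(rbind(loci, ""))), collapse = "\t")
  writeLines(c(header, vapply(rows, paste, "", collapse = "\t")), path)
}

# random rooted tree whose groups are perfect clades
random_monophyletic_tree <- function(n_groups, sizes) {
  subtrees <- lapply(seq_len(n_groups), function(g) {
    labs <- sprintf("g%d_%d", g, seq_len(sizes[g]))
    if (sizes[g] == 1L) return(labs)
    tr <- ape::rtree(sizes[g], tip.label = labs)
    sub(";$", "", ape::write.tree(tr))
  })
  txt <- paste0("(", paste(unlist(subtrees), collapse = ","), ");")
  tree <- ape::read.tree(text = txt)
  labels <- stats::setNames(
    rep(sprintf("G%d", seq_len(n_groups)), sizes),
    unlist(lapply(seq_len(n_groups), function(g)
      sprintf("g%d_%d", g, seq_len(sizes[g])))))
  list(tree = tree, labels = labels)
}

# brute-force split set of a tree: for every internal edge, the sorted
# side not containing the alphabetically first label
oracle_splits <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- ape::Ntip(tree)
  labs <- sort(tree$tip.label)
  out <- character()
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2L]
    if (ch <= ntip) next
    side <- tree$tip.label[unlist(phangorn::Descendants(tree, ch, "tips"))]
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    if (labs[1L] %in% side) side <- setdiff(labs, side)
    out <- c(out, paste(sort(side), collapse = ","))
  }
  unique(out)
}
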