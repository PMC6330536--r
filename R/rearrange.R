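#' Describe interchromosomal translocations to inject into a simulation
#'
#' Each event moves a contiguous block of at least three genes (so that the
#' downstream ">= 3 syntenic markers" detection rule can see it) from a
#' source chromosome to an insertion point on a target chromosome.  Events
#' with scope `"shared"` are applied to both simulated species' genomes,
#' modelling rearrangements that predate their speciation; scope `"A"` or
#' `"B"` applies to one species only.
#'
#' Gene blocks are addressed by 1-based index within the source
#' chromosome's gene order in the *base* reference, and `insert_after` by
#' index within the target chromosome (0 inserts at the start).  To keep
#' the bookkeeping unambiguous, source intervals must not overlap within a
#' species and no chromosome may serve as both source and target within a
#' species.
#'
#' @param src_chrom,dst_chrom Source/target chromosome names.
#' @param from_gene 1-based index of the first moved gene on `src_chrom`.
#' @param n_genes Number of genes moved (>= 3).
#' @param insert_after Gene index on `dst_chrom` after which the block is
#'   inserted.
#' @param scope `"shared"`, `"A"` or `"B"`.
#' @return A data.frame of class `rearrangement_plan`.
#' @export
rearrangement_plan <- function(src_chrom, from_gene, n_genes,
                               dst_chrom, insert_after,
                               scope = "shared") {
  plan <- data.frame(src_chrom = src_chrom, from_gene = as.integer(from_gene),
                     n_genes = as.integer(n_genes), dst_chrom = dst_chrom,
                     insert_after = as.integer(insert_after),
                     scope = scope, stringsAsFactors = FALSE)
  if (any(plan$n_genes < 3))
    stop("each event must move at least 3 genes", call. = FALSE)
  if (any(plan$src_chrom == plan$dst_chrom))
    stop("source and target chromosomes must differ", call. = FALSE)
  if (!all(plan$scope %in% c("shared", "A", "B")))
    stop('`scope` must be "shared", "A" or "B"', call. = FALSE)
  for (sp in c("A", "B")) {
    sub <- plan[plan$scope %in% c("shared", sp), , drop = FALSE]
    if (any(sub$dst_chrom %in% sub$src_chrom))
      stop("a chromosome cannot be both source and target within a species",
           call. = FALSE)
    for (ch in unique(sub$src_chrom)) {
      iv <- sub[sub$src_chrom == ch, , drop = FALSE]
      iv <- iv[order(iv$from_gene), , drop = FALSE]
      if (nrow(iv) > 1 &&
          any(head(iv$from_gene + iv$n_genes, -1) > tail(iv$from_gene, -1)))
        stop("overlapping source intervals on ", ch, call. = FALSE)
    }
  }
  class(plan) <- c("rearrangement_plan", "data.frame")
  plan
}

#' Apply a translocation plan to two species' genomes
#'
#' Shared events are applied to both species, private events to one.  Gene
#' coordinates are re-laid out after the moves; gene identities (and hence
#' the anchor table, which always reports base-reference positions) are
#' untouched, so moved genes *reside* on the target chromosome in the
#' species while *anchoring* to their original chromosome.
#'
#' @param ref_a,ref_b `octo_reference` objects for the two species
#'   (typically both the same base reference from [build_reference()]).
#' @param plan A [rearrangement_plan()] (or `NULL` for no events).
#' @return A list with rearranged `ref_a`, `ref_b`, and `events`: the truth
#'   table (`event_id`, `species`, `src_chrom`, `dst_chrom`, `shared`,
#'   `gene_ids`).
#' @export
inject_rearrangements <- function(ref_a, ref_b, plan = NULL) {
  stopifnot(inherits(ref_a, "octo_reference"),
            inherits(ref_b, "octo_reference"))
  if (is.null(plan) || nrow(plan) == 0) {
    events <- data.frame(event_id = character(0), species = character(0),
                         src_chrom = character(0), dst_chrom = character(0),
                         shared = logical(0), gene_ids = character(0),
                         stringsAsFactors = FALSE)
    return(list(ref_a = ref_a, ref_b = ref_b, events = events))
  }
  stopifnot(inherits(plan, "rearrangement_plan"))
  ev_list <- list()
  for (sp in c("A", "B")) {
    base <- if (sp == "A") ref_a else ref_b
    sub <- plan[plan$scope %in% c("shared", sp), , drop = FALSE]
    if (nrow(sub) == 0) next
    moved <- apply_moves(base, sub)
    if (sp == "A") ref_a <- moved$ref else ref_b <- moved$ref
    ev_list[[sp]] <- data.frame(
      event_id = sprintf("%s_ev%02d", sp, seq_len(nrow(sub))),
      species = sp, src_chrom = sub$src_chrom, dst_chrom = sub$dst_chrom,
      shared = sub$scope == "shared", gene_ids = moved$gene_ids,
      stringsAsFactors = FALSE)
  }
  list(ref_a = ref_a, ref_b = ref_b, events = do.call(rbind, ev_list))
}

# Execute the moves of `sub` on one species' reference.
apply_moves <- function(ref, sub) {
  orders <- split(ref$genes$gene_id, ref$genes$chrom)
  gene_ids <- character(nrow(sub))
  blocks <- vector("list", nrow(sub))
  for (i in seq_len(nrow(sub))) {
    src <- orders[[sub$src_chrom[i]]]
    idx <- sub$from_gene[i]:(sub$from_gene[i] + sub$n_genes[i] - 1L)
    if (max(idx) > length(src))
      stop("event ", i, " exceeds genes on ", sub$src_chrom[i], call. = FALSE)
    blocks[[i]] <- src[idx]
    gene_ids[i] <- paste(src[idx], collapse = ",")
  }
  all_moved <- unlist(blocks)
  for (ch in names(orders))        # drop moved genes from their sources
    orders[[ch]] <- setdiff(orders[[ch]], all_moved)
  for (i in seq_len(nrow(sub))) {  # insert blocks into (unchanged) targets
    dst <- orders[[sub$dst_chrom[i]]]
    at <- min(sub$insert_after[i], length(dst))
    orders[[sub$dst_chrom[i]]] <- append(dst, blocks[[i]], after = at)
  }
  new_order <- unlist(orders, use.names = FALSE)
  genes <- ref$genes[match(new_order, ref$genes$gene_id), , drop = FALSE]
  genes$chrom <- rep(names(orders), lengths(orders))
  rownames(genes) <- NULL
  genes <- layout_genes(genes, nchar(ref$cds[genes$gene_id]),
                        ref$intergenic_bp)
  ref$genes <- genes
  ref$chromosomes <- chrom_lengths(genes, ref$intergenic_bp,
                                   ref$chromosomes$chrom)
  list(ref = ref, gene_ids = gene_ids)
}

#' Anchor table of a reference
#'
#' Maps every gene to its chromosome and interval in the given reference.
#' Built from the *base* reference this is the synteny anchor table handed
#' to [assign_hg()]; positions are reported 1-based inclusive.
#'
#' @param ref An `octo_reference`.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end` (1-based).
#' @export
anchor_table <- function(ref) {
  stopifnot(inherits(ref, "octo_reference"))
  data.frame(gene_id = ref$genes$gene_id, chrom = ref$genes$chrom,
             start = ref$genes$start + 1L, end = ref$genes$end,
             stringsAsFactors = FALSE)
}

#' Marker-level anchors against the base reference
#'
#' Resolves marker ids of the form `gene:pos` through a gene anchor table
#' so that every marker reports the base-reference chromosome and position
#' of its gene model — the input [assign_hg()] and [detect_events()]
#' expect.
#'
#' @param marker_ids Character vector `"<gene_id>:<pos>"`.
#' @param anchors Gene anchor table from [anchor_table()].
#' @return data.frame: `marker_id`, `chrom`, `start`.
#' @export
marker_anchors <- function(marker_ids, anchors) {
  gene <- sub(":[0-9]+$", "", marker_ids)
  pos <- as.integer(sub("^.*:", "", marker_ids))
  j <- match(gene, anchors$gene_id)
  data.frame(marker_id = marker_ids, chrom = anchors$chrom[j],
             start = anchors$start[j] + pos - 1L, stringsAsFactors = FALSE)
}
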