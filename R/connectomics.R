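# Connectivity summaries of EM synapse tables: fraction of total input,
# strong-partner filtering, fragment flagging, synaptic hop distances.

#' Read / write synapse tables as CSV pairs
#'
#' Edges CSV: pre_id, post_id, synapse_count, connection_type.  Neurons CSV:
#' id, name, class, side, hemilateral_partner_id, node_count, neuromere.
#' A loader convention infers missing side / hemilateral partner ids from
#' the CATMAID-style \code{_l}/\code{_r} name suffixes.
#'
#' @param edges_path,neurons_path file paths.
#' @param infer_pairs infer side and partner ids from id suffixes when the
#'   columns are absent.
#' @return a \code{synapse_table}.
#' @export
read_synapse_table <- function(edges_path, neurons_path,
                               infer_pairs = TRUE) {
  edges <- utils::read.csv(edges_path, stringsAsFactors = FALSE)
  neurons <- utils::read.csv(neurons_path, stringsAsFactors = FALSE)
  if (infer_pairs && is.null(neurons$side)) {
    suf <- sub("^.*(_[lr])$", "\\1", neurons$id)
    neurons$side <- ifelse(suf == "_l", "l", ifelse(suf == "_r", "r",
                                                    "unknown"))
  }
  if (infer_pairs && is.null(neurons$hemilateral_partner_id)) {
    flip <- ifelse(grepl("_l$", neurons$id), sub("_l$", "_r", neurons$id),
                   ifelse(grepl("_r$", neurons$id),
                          sub("_r$", "_l", neurons$id), NA))
    neurons$hemilateral_partner_id <- ifelse(flip %in% neurons$id, flip, NA)
  }
  synapse_table(edges, neurons)
}

#' @rdname read_synapse_table
#' @param table a \code{synapse_table} to serialize.
#' @export
write_synapse_table <- function(table, edges_path, neurons_path) {
  utils::write.csv(table$edges, edges_path, row.names = FALSE)
  utils::write.csv(table$neurons, neurons_path, row.names = FALSE)
  invisible(c(edges_path, neurons_path))
}

#' Fraction of total input
#'
#' For a target neuron (or pooled hemilateral pair), the synapse count
#' received from each partner -- or each partner class -- divided by the
#' target's total incoming synapse count.  Fractions sum to 1 over all
#' groups, fragments and unreconstructed inputs included.
#'
#' @param table a \code{synapse_table}.
#' @param target_ids character: the target neuron(s); inputs are pooled.
#' @param group_by \code{"partner"} (by presynaptic neuron name, pooling
#'   left/right homologs) or \code{"class"}.
#' @param connection_types optional filter on connection type (default all
#'   types pooled).
#' @return named numeric vector of fractions, summing to 1; total synapse
#'   count in \code{attr(, "total")}.
#' @export
fraction_of_input <- function(table, target_ids,
                              group_by = c("partner", "class"),
                              connection_types = NULL) {
  group_by <- match.arg(group_by)
  unknown <- setdiff(target_ids, table$neurons$id)
  if (length(unknown)) stop("unknown target id(s): ",
                            paste(unknown, collapse = ", "))
  e <- table$edges[table$edges$post_id %in% target_ids, , drop = FALSE]
  if (!is.null(connection_types))
    e <- e[e$connection_type %in% connection_types, , drop = FALSE]
  if (!nrow(e)) stop("target has no incoming synapses")
  nrn <- table$neurons
  key <- if (group_by == "class") {
    nrn$class[match(e$pre_id, nrn$id)]
  } else {
    nm <- nrn$name[match(e$pre_id, nrn$id)]
    ifelse(is.na(nm) | nm == "", e$pre_id, nm)
  }
  tot <- sum(e$synapse_count)
  fr <- tapply(e$synapse_count, key, sum) / tot
  out <- sort(c(fr), decreasing = TRUE)
  attr(out, "total") <- tot
  out
}

#' Strong synaptic partners of a hemilateral pair
#'
#' A partner is strong if at least one member of the hemilateral pair of
#' neurons makes/receives at least \code{min_synapses} synapses with it:
#' the threshold applies to the maximum over the pair.
#'
#' @param table a \code{synapse_table}.
#' @param pair_ids the hemilateral pair (or a singleton).
#' @param direction \code{"down"}: partners receiving synapses from the
#'   pair; \code{"up"}: partners sending synapses to the pair.
#' @param min_synapses threshold (default 3).
#' @return data frame (partner_id, max_synapses) of strong partners.
#' @export
strong_partners <- function(table, pair_ids, direction = c("down", "up"),
                            min_synapses = 3) {
  direction <- match.arg(direction)
  unknown <- setdiff(pair_ids, table$neurons$id)
  if (length(unknown)) stop("unknown id(s): ", paste(unknown, collapse = ", "))
  e <- table$edges
  if (direction == "down") {
    e <- e[e$pre_id %in% pair_ids, , drop = FALSE]
    partner <- e$post_id
  } else {
    e <- e[e$post_id %in% pair_ids, , drop = FALSE]
    partner <- e$pre_id
  }
  if (!nrow(e))
    return(data.frame(partner_id = character(0), max_synapses = integer(0)))
  # max over the pair: per (partner, pair member) sums, then max per partner
  member <- if (direction == "down") e$pre_id else e$post_id
  per <- tapply(e$synapse_count, list(partner, member), sum)
  mx <- apply(per, 1, max, na.rm = TRUE)
  keep <- mx >= min_synapses
  out <- data.frame(partner_id = names(mx)[keep],
                    max_synapses = unname(mx[keep]),
                    stringsAsFactors = FALSE)
  out[order(-out$max_synapses, out$partner_id), , drop = FALSE]
}

#' Flag fragment (not reconstructed up to recognition) neurons
#'
#' Neurons with fewer than \code{node_threshold} skeleton nodes are flagged
#' as fragments, except sensory neurons (which are recognizable from their
#' entry point regardless of reconstruction depth).  Fragments are excluded
#' from named-partner listings but stay in input-fraction denominators.
#'
#' @param table a \code{synapse_table}.
#' @param node_threshold strict lower bound on node_count (default 1500).
#' @return the table with a logical \code{fragment} column on neurons.
#' @export
flag_fragments <- function(table, node_threshold = 1500) {
  n <- table$neurons
  n$fragment <- n$node_count < node_threshold & n$class != "sensory"
  table$neurons <- n
  table
}

#' Synaptic hop distances over strong connections
#'
#' Shortest directed path length (in hops) from each source to each target
#' over the graph restricted to edges with at least \code{min_synapses}
#' synapses; unreachable pairs get \code{Inf}.
#'
#' @param table a \code{synapse_table}.
#' @param source_ids,target_ids neuron ids.
#' @param min_synapses edge-inclusion threshold (default 3).
#' @return numeric matrix (sources x targets) of hop counts.
#' @export
synaptic_distance <- function(table, source_ids, target_ids,
                              min_synapses = 3) {
  e <- table$edges[table$edges$synapse_count >= min_synapses, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    e[, c("pre_id", "post_id")], directed = TRUE,
    vertices = data.frame(name = table$neurons$id))
  d <- igraph::distances(g, v = source_ids, to = target_ids, mode = "out")
  d
}

#' Group motor neurons by synaptic distance from two seed neurons
#'
#' Motor neurons are grouped by the ordered pair of hop distances (distance
#' from each seed), the grouping used to lay out motor targets by their
#' distance to a descending neuron and a second-order interneuron.
#'
#' @param table a \code{synapse_table}.
#' @param seeds character vector of two seed neuron ids (or id vectors in a
#'   list, pooled by minimum distance).
#' @param min_synapses edge-inclusion threshold.
#' @return data frame (motor_id, dist_seed1, dist_seed2, group).
#' @export
motor_group <- function(table, seeds, min_synapses = 3) {
  if (!is.list(seeds)) seeds <- as.list(seeds)
  stopifnot(length(seeds) == 2)
  motors <- table$neurons$id[table$neurons$class == "motor"]
  if (!length(motors)) stop("no motor neurons in table")
  d1 <- synaptic_distance(table, seeds[[1]], motors, min_synapses)
  d2 <- synaptic_distance(table, seeds[[2]], motors, min_synapses)
  dd1 <- apply(d1, 2, min); dd2 <- apply(d2, 2, min)
  grp <- paste0("(", ifelse(is.finite(dd1), dd1, "inf"), ",",
                ifelse(is.finite(dd2), dd2, "inf"), ")")
  data.frame(motor_id = motors, dist_seed1 = dd1, dist_seed2 = dd2,
             group = grp, stringsAsFactors = FALSE, row.names = NULL)
}
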