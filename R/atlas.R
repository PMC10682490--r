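#' Node-to-network brain partitions
#'
#' A partition assigns each of the N nodes (regions of interest) of a
#' connectome to exactly one named resting-state network (RSN). The default
#' fixture shipped with the package, `power226.tsv`, is a synthetic but
#' structurally faithful 226-node, 10-network partition (network names AUD,
#' CON, DAN, DMN, FPN, SAN, SMN, SUB, VAN, VIS with plausible sizes); it is
#' *not* a claim about the true ROI-to-network assignment of any published
#' atlas, which is why it lives in the package rather than being downloaded.
#'
#' Node ids are 1-based in all files and in the `node_id` column; row order
#' of the partition file defines node order everywhere downstream.
#'
#' @param df A data frame with columns `node_id` (unique integers) and
#'   `network` (non-empty network name per node).
#' @return A tibble of class `sg_partition` with columns `node_id` and
#'   `network`, plus an attribute `network_names` giving the networks in
#'   first-appearance order.
#' @examples
#' p <- as_partition(data.frame(node_id = 1:4, network = c("A", "A", "B", "B")))
#' network_names(p)
#' @export
as_partition <- function(df) {
  if (!all(c("node_id", "network") %in% names(df))) {
    stop_sg("partition needs columns 'node_id' and 'network'")
  }
  node_id <- as.integer(df$node_id)
  network <- as.character(df$network)
  if (anyNA(node_id) || anyNA(network)) stop_sg("partition contains missing values")
  if (anyDuplicated(node_id)) {
    dup <- node_id[duplicated(node_id)]
    stop_sg("duplicate node id(s) in partition: ", paste(unique(dup), collapse = ", "))
  }
  if (any(!nzchar(network))) stop_sg("empty network name in partition")
  nets <- unique(network)
  if (length(nets) < 2L) stop_sg("partition must contain at least 2 networks")
  out <- tibble::tibble(node_id = node_id, network = network)
  attr(out, "network_names") <- nets
  class(out) <- c("sg_partition", class(out))
  out
}

#' @rdname as_partition
#' @param path Path to a delimited text file with two columns
#'   (`node_id`, `network`); a header line is detected automatically.
#' @export
read_partition <- function(path) {
  raw <- utils::read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
                           col.names = c("node_id", "network"),
                           colClasses = "character")
  if (nrow(raw) == 0L) stop_sg("empty partition file: ", path)
  if (is.na(suppressWarnings(as.integer(raw$node_id[1])))) raw <- raw[-1, , drop = FALSE]
  ids <- suppressWarnings(as.integer(raw$node_id))
  if (anyNA(ids)) stop_sg("non-integer node id in partition file: ", path)
  as_partition(data.frame(node_id = ids, network = raw$network))
}

#' @rdname as_partition
#' @export
default_partition <- function() {
  read_partition(system.file("extdata", "power226.tsv", package = "suigrad"))
}

#' @rdname as_partition
#' @param partition An `sg_partition`.
#' @export
network_names <- function(partition) attr(partition, "network_names")

# node indices (positions in file order) per network, as a named list
network_index <- function(partition) {
  split(seq_len(nrow(partition)), factor(partition$network, levels = network_names(partition)))
}

#' Suicidality group labels
#'
#' The six ordered study groups: healthy controls and five depression
#' subgroups graded by the 17-item HAMD suicide item (0-4): no suicidal
#' ideation (MDDNSI), mild (MDDmSI), moderate (MDDmoSI), severe (MDDSSI)
#' suicidal ideation, and suicidal behaviour (MDDSB).
#'
#' @return Character vector of the six group labels in gradient order.
#' @export
suicidality_groups <- function() {
  c("HC", "MDDNSI", "MDDmSI", "MDDmoSI", "MDDSSI", "MDDSB")
}

#' Map HAMD suicide-item scores to suicidality groups
#'
#' Patients are assigned by their HAMD suicide-item score (0 to 4:
#' MDDNSI, MDDmSI, MDDmoSI, MDDSSI, MDDSB); non-patients are `HC`.
#'
#' @param hamd_suicide Integer score(s) in 0..4 (ignored, may be `NA`, for
#'   non-patients).
#' @param is_patient Logical, recycled against `hamd_suicide`.
#' @return Factor with levels `suicidality_groups()`.
#' @examples
#' assign_suicidality_group(c(0, 4, NA), c(TRUE, TRUE, FALSE))
#' @export
assign_suicidality_group <- function(hamd_suicide, is_patient) {
  n <- max(length(hamd_suicide), length(is_patient))
  hamd_suicide <- rep_len(hamd_suicide, n)
  is_patient <- rep_len(as.logical(is_patient), n)
  s <- hamd_suicide[is_patient]
  if (anyNA(s) || any(s != as.integer(s)) || any(s < 0 | s > 4)) {
    stop_sg("hamd_suicide must be an integer in 0..4 for patients")
  }
  groups <- suicidality_groups()
  out <- rep(groups[1L], n)
  out[is_patient] <- groups[hamd_suicide[is_patient] + 2L]
  factor(out, levels = groups)
}

#' Head-motion quality control
#'
#' Retains subjects whose mean framewise displacement (FD) does not exceed
#' `fd_threshold`; subjects with mean FD strictly above the threshold are
#' excluded, following the usual 0.2 mm convention.
#'
#' @param subjects Data frame with at least `subject_id` and `mean_fd`
#'   (millimetres) columns.
#' @param fd_threshold Exclusion threshold in millimetres (default 0.2).
#' @return List with `retained` (tibble of surviving rows) and `exclusions`
#'   (tibble `subject_id`, `mean_fd`, `reason`).
#' @export
qc_filter <- function(subjects, fd_threshold = 0.2) {
  stopifnot(is.data.frame(subjects))
  if (!all(c("subject_id", "mean_fd") %in% names(subjects))) {
    stop_sg("subjects needs 'subject_id' and 'mean_fd' columns")
  }
  if (anyNA(subjects$mean_fd)) {
    bad <- subjects$subject_id[is.na(subjects$mean_fd)]
    stop_sg("missing mean_fd for subject(s): ", paste(bad, collapse = ", "))
  }
  keep <- subjects$mean_fd <= fd_threshold
  exclusions <- tibble::tibble(
    subject_id = subjects$subject_id[!keep],
    mean_fd = subjects$mean_fd[!keep],
    reason = sprintf("mean FD %.4g mm > %.4g mm", subjects$mean_fd[!keep], fd_threshold)
  )
  list(retained = tibble::as_tibble(subjects[keep, , drop = FALSE]),
       exclusions = exclusions)
}
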