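#' Network role taxonomy
#'
#' Classifies each network, per group, into one of four roles from its
#' group-mean within-network connectivity (WNC) and one-versus-others
#' connectivity (OVO): *cohesive* (WNC at or above the cohesion cut) vs
#' *incohesive*, crossed with *connector* (OVO at or above the connector
#' cut) vs *province*. With the default `"median"` policy each cut is the
#' median of the ten values within the group, the least-parameterised
#' reading of a distribution-based split; ties land on the cohesive /
#' connector side (`>=`). The cuts used are recorded in the output so
#' every assignment is auditable.
#'
#' @param group_summary Tibble with columns `group`, `metric_type`
#'   (containing `"wnc"` and `"ovo"` rows), `net_a` and `value`, e.g. from
#'   [summarize_groups()].
#' @param policy `"median"` (per-group median split) or `"fixed"`.
#' @param wnc_cut,ovo_cut Fixed cuts, required when `policy = "fixed"`.
#' @return Tibble of class `sg_roles`: `group`, `network`, `wnc`, `ovo`,
#'   `wnc_cut`, `ovo_cut`, `role` (one of "cohesive connector",
#'   "cohesive province", "incohesive connector", "incohesive province").
#' @export
assign_roles <- function(group_summary, policy = c("median", "fixed"),
                         wnc_cut = NULL, ovo_cut = NULL) {
  policy <- match.arg(policy)
  if (policy == "fixed" && (is.null(wnc_cut) || is.null(ovo_cut))) {
    stop_sg("policy 'fixed' requires wnc_cut and ovo_cut")
  }
  stopifnot(all(c("group", "metric_type", "net_a", "value") %in% names(group_summary)))
  wide <- group_summary |>
    dplyr::filter(.data$metric_type %in% c("wnc", "ovo")) |>
    dplyr::select("group", "metric_type", network = "net_a", "value") |>
    tidyr::pivot_wider(names_from = "metric_type", values_from = "value")
  if (anyNA(wide$wnc) || anyNA(wide$ovo)) {
    stop_sg("need both WNC and OVO values for every (group, network)")
  }
  out <- wide |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(
      wnc_cut = if (policy == "median") stats::median(.data$wnc) else wnc_cut,
      ovo_cut = if (policy == "median") stats::median(.data$ovo) else ovo_cut,
      role = paste(ifelse(.data$wnc >= .data$wnc_cut, "cohesive", "incohesive"),
                   ifelse(.data$ovo >= .data$ovo_cut, "connector", "province"))
    ) |>
    dplyr::ungroup()
  class(out) <- c("sg_roles", class(out))
  out
}

#' Role trajectory across the suicidality gradient
#'
#' Orders each network's role assignments along the group gradient and
#' flags networks whose role changes between groups (*divergent*) versus
#' networks holding one role throughout (*stable*).
#'
#' @param roles An [assign_roles()] tibble covering several groups; every
#'   group must cover the same network set.
#' @param group_order Group ordering, default [suicidality_groups()]
#'   restricted to the groups present.
#' @return List with `trajectory` (tibble `network`, `group`, `role`,
#'   `wnc`, `ovo`, ordered by `group_order`) and `stability` (tibble
#'   `network`, `stable`, `n_roles`, `role_sequence`).
#' @export
role_trajectory <- function(roles, group_order = NULL) {
  stopifnot(inherits(roles, "sg_roles") || is.data.frame(roles))
  groups_present <- unique(as.character(roles$group))
  group_order <- group_order %||% intersect(suicidality_groups(), groups_present)
  if (!setequal(group_order, groups_present)) {
    stop_sg("group_order must cover exactly the groups present: ",
            paste(groups_present, collapse = ", "))
  }
  nets_by_group <- split(roles$network, as.character(roles$group))
  ref <- sort(nets_by_group[[1]])
  same <- vapply(nets_by_group, function(x) identical(sort(x), ref), logical(1))
  if (!all(same)) stop_sg("network sets differ across groups")

  trajectory <- roles |>
    dplyr::mutate(group = factor(.data$group, levels = group_order)) |>
    dplyr::arrange(.data$network, .data$group) |>
    dplyr::select("network", "group", "role", "wnc", "ovo")
  stability <- trajectory |>
    dplyr::group_by(.data$network) |>
    dplyr::summarise(n_roles = dplyr::n_distinct(.data$role),
                     stable = .data$n_roles == 1L,
                     role_sequence = paste(.data$role, collapse = " -> "),
                     .groups = "drop")
  list(trajectory = trajectory, stability = stability)
}
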