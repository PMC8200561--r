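#' Branched myelinated fiber morphology
#'
#' Builds the compartment tree of a thin myelinated fiber: a stem axon whose
#' proximal end (the recording point, toward the trigeminal ganglion) is the
#' root, joined at its distal end by branches of alternating nodes of Ranvier
#' and myelinated internodes, each branch ending in a thin unmyelinated
#' terminal region carrying the receptor pools. One table row per
#' compartment: `section_id`, `parent_id` (NA for the root), `kind`
#' (`node`, `internode`, `terminal`), `length_um`, `diameter_um` — a flat-file
#' subset of SWC-style morphology conventions.
#'
#' @param n_branches Number of distal branches (default 2).
#' @param branch_length_um Length of each branch (default 1.1 cm).
#' @param stem_length_um Length of the parent axon.
#' @param internode_length_um Myelinated internode length between nodes.
#' @param node_length_um,node_diameter_um Node of Ranvier geometry (2 x 2 um).
#' @param fiber_diameter_um Internode (fiber) diameter (5 um for A-delta).
#' @param terminal_length_um,terminal_diameter_um,terminal_nseg Unmyelinated
#'   terminal geometry and its number of compartments.
#' @return A tibble of compartments (class `fiber_morphology`), with attribute
#'   `terminals` naming the distal compartment of each branch
#'   (`terminal_1`, `terminal_2`, ...).
#' @export
branched_morphology <- function(n_branches = 2, branch_length_um = 11000,
                                stem_length_um = 11000,
                                internode_length_um = 200,
                                node_length_um = 2, node_diameter_um = 2,
                                fiber_diameter_um = 5,
                                terminal_length_um = 200,
                                terminal_diameter_um = 1, terminal_nseg = 4) {
  rows <- list()
  add <- function(parent, kind, len, diam) {
    id <- length(rows) + 1L
    rows[[id]] <<- list(section_id = id, parent_id = parent, kind = kind,
                        length_um = len, diameter_um = diam)
    id
  }
  myelinated_run <- function(parent, total_um) {
    n_units <- max(1L, round(total_um / (node_length_um + internode_length_um)))
    last <- parent
    for (i in seq_len(n_units)) {
      last <- add(last, "node", node_length_um, node_diameter_um)
      last <- add(last, "internode", internode_length_um, fiber_diameter_um)
    }
    last
  }
  # stem: root node (recording point) then alternating internode/node units
  root <- add(NA_integer_, "node", node_length_um, node_diameter_um)
  junction <- myelinated_run(root, stem_length_um)
  terminals <- integer(n_branches)
  for (b in seq_len(n_branches)) {
    last <- myelinated_run(junction, branch_length_um)
    for (s in seq_len(terminal_nseg)) {
      last <- add(last, "terminal", terminal_length_um / terminal_nseg,
                  terminal_diameter_um)
    }
    terminals[b] <- last
  }
  names(terminals) <- paste0("terminal_", seq_len(n_branches))
  out <- dplyr::bind_rows(rows)
  structure(as_tibble(out), terminals = terminals, recording = root,
            class = c("fiber_morphology", class(out)))
}

#' Unbranched unmyelinated morphology (C-fiber stand-in)
#'
#' @param length_um Total cable length.
#' @param segment_um Compartment length.
#' @param diameter_um Cable diameter.
#' @return A `fiber_morphology` tibble; every compartment is active
#'   (`kind = "node"`), the distal compartment is `terminal_1`.
#' @export
unmyelinated_morphology <- function(length_um = 5000, segment_um = 100,
                                    diameter_um = 0.8) {
  n <- max(2L, round(length_um / segment_um))
  out <- tibble(
    section_id = seq_len(n),
    parent_id = c(NA_integer_, seq_len(n - 1L)),
    kind = c(rep("node", n - 1L), "terminal"),
    length_um = segment_um,
    diameter_um = diameter_um
  )
  structure(out, terminals = c(terminal_1 = n), recording = 1L,
            class = c("fiber_morphology", class(out)))
}

#' Read or write a morphology table
#'
#' @param path CSV file with columns `section_id`, `parent_id`, `kind`,
#'   `length_um`, `diameter_um`.
#' @return For `read_morphology()`, a `fiber_morphology` tibble (the recording
#'   point is the root; terminals are the `terminal` compartments in order).
#' @export
read_morphology <- function(path) {
  df <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_morphology(df)
  term_ids <- df$section_id[df$kind == "terminal" &
                              !df$section_id %in% df$parent_id]
  names(term_ids) <- paste0("terminal_", seq_along(term_ids))
  structure(df, terminals = term_ids,
            recording = df$section_id[is.na(df$parent_id)][1],
            class = c("fiber_morphology", class(df)))
}

#' @rdname read_morphology
#' @param morphology A `fiber_morphology` tibble.
#' @export
write_morphology <- function(morphology, path) {
  utils::write.csv(as.data.frame(morphology)[, c("section_id", "parent_id",
                                                 "kind", "length_um",
                                                 "diameter_um")],
                   path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

validate_morphology <- function(df) {
  if (sum(is.na(df$parent_id)) != 1) abort("Morphology must have exactly one root.")
  if (any(!is.na(df$parent_id) & df$parent_id >= df$section_id)) {
    abort("Compartments must be ordered parent before child.")
  }
  invisible(df)
}
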