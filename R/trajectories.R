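# Allele-frequency trajectories across sequenced timepoints and
# populations: merging calls, fixation/loss classification, parallelism,
# clonal interference, and Muller-table export.

#' Build an allele-by-timepoint frequency table from per-timepoint calls
#'
#' Calls from successive timepoints are merged into one allele when their
#' keys (family/mutation class, contig, orientation) match and their
#' sites differ by at most `site_tolerance`; the lowest coordinate wins
#' as the canonical site. Conflicting orientations at one site remain
#' distinct alleles. Timepoints where an allele was not detected are
#' `NA` — the data cannot distinguish absence from sub-detection-limit
#' presence, so `NA` is deliberately not 0.
#'
#' @param call_sets Named list (names = timepoints, e.g. generations) of
#'   call data frames with columns `family`, `contig`, `site`,
#'   `orientation`, `frequency` (e.g. [call_insertions()] output;
#'   non-PASS calls should be filtered by the caller beforehand if
#'   desired).
#' @param site_tolerance Maximum site distance for cross-timepoint
#'   matching.
#' @return Object of class `trajectory_table`: data frame with allele key
#'   columns (allele, family, contig, site, orientation) and one
#'   frequency column per timepoint (`t_<timepoint>`).
#' @export
build_trajectories <- function(call_sets, site_tolerance = 5) {
  stopifnot(length(call_sets) >= 1, !is.null(names(call_sets)))
  tps <- names(call_sets)
  alleles <- NULL  # running canonical allele table
  freq <- list()
  for (tp in tps) {
    cs <- call_sets[[tp]]
    fr <- rep(NA_real_, if (is.null(alleles)) 0 else nrow(alleles))
    if (!is.null(cs) && nrow(cs)) {
      for (i in seq_len(nrow(cs))) {
        hit <- if (!is.null(alleles))
          which(alleles$family == cs$family[i] &
                  alleles$contig == cs$contig[i] &
                  alleles$orientation == cs$orientation[i] &
                  abs(alleles$site - cs$site[i]) <= site_tolerance)
        else integer(0)
        if (length(hit)) {
          hit <- hit[which.min(abs(alleles$site[hit] - cs$site[i]))]
          # lowest coordinate wins as the canonical site
          if (cs$site[i] < alleles$site[hit]) {
            alleles$site[hit] <- cs$site[i]
          }
          fr[hit] <- max(fr[hit], cs$frequency[i], na.rm = TRUE)
        } else {
          alleles <- rbind(alleles, data.frame(
            family = cs$family[i], contig = cs$contig[i],
            site = cs$site[i], orientation = cs$orientation[i],
            stringsAsFactors = FALSE))
          fr <- c(fr, cs$frequency[i])
          # extend earlier timepoints with NA
          for (old in names(freq))
            freq[[old]] <- c(freq[[old]], NA_real_)
        }
      }
    }
    freq[[tp]] <- fr
  }
  n <- if (is.null(alleles)) 0 else nrow(alleles)
  out <- if (n) cbind(
    data.frame(allele = sprintf("%s_%s_%d_%s", alleles$family,
                                alleles$contig, alleles$site,
                                alleles$orientation),
               alleles, stringsAsFactors = FALSE),
    stats::setNames(as.data.frame(freq[tps]), paste0("t_", tps)))
  else data.frame(allele = character(0), family = character(0),
                  contig = character(0), site = integer(0),
                  orientation = character(0))
  rownames(out) <- NULL
  structure(out, timepoints = as.numeric(tps),
            class = c("trajectory_table", "data.frame"))
}

traj_freq_matrix <- function(table) {
  fc <- grep("^t_", names(table), value = TRUE)
  m <- as.matrix(table[, fc, drop = FALSE])
  rownames(m) <- table$allele
  colnames(m) <- sub("^t_", "", fc)
  m
}

#' Classify alleles as fixed, lost, segregating or transient
#'
#' Fixed: final frequency at or above `fixed_threshold` ("fixed or near
#' fixation"). Lost: detected at or above `detect_threshold` at some
#' timepoint but below it (or undetected) at the final one. Segregating:
#' currently detected, neither fixed nor lost. Transient: never reached
#' the detection threshold.
#'
#' @param table A `trajectory_table` (or data frame with `t_*` columns).
#' @param fixed_threshold Final frequency for "fixed (or near fixation)".
#' @param detect_threshold Detection cutoff.
#' @return The table with a `status` column appended.
#' @export
classify_alleles <- function(table, fixed_threshold = 0.95,
                             detect_threshold = 0.02) {
  m <- traj_freq_matrix(table)
  status <- apply(m, 1, function(f) {
    fin <- f[length(f)]
    detected <- !is.na(f) & f >= detect_threshold
    if (!is.na(fin) && fin >= fixed_threshold) "fixed"
    else if (any(detected) && (is.na(fin) || fin < detect_threshold))
      "lost"
    else if (any(detected)) "segregating"
    else "transient"
  })
  table$status <- unname(status)
  table
}

#' Fixed insertions per 1,000 total generations
#'
#' @param statuses Character vector of allele statuses (across all
#'   populations) or a classified `trajectory_table`.
#' @param total_generations Sum of generations over all populations
#'   (e.g. 8 populations x 400 generations = 3200).
#' @return `1000 * n_fixed / total_generations`.
#' @export
fixation_rate <- function(statuses, total_generations) {
  if (is.data.frame(statuses)) statuses <- statuses$status
  if (total_generations <= 0) stop("total generations must be positive")
  1000 * sum(statuses == "fixed") / total_generations
}

#' Parallelism of alleles and loci across populations
#'
#' @param tables Named list (population -> `trajectory_table`).
#' @param locus_map Optional function or named vector mapping an allele
#'   key to a locus label; by default the locus is `contig` plus the site
#'   rounded down to a 1 kb window.
#' @return List with `alleles` (allele, n_populations) and `loci`
#'   (locus, n_populations), both sorted descending.
#' @export
parallelism <- function(tables, locus_map = NULL) {
  stopifnot(length(tables) >= 2)
  per_pop <- lapply(names(tables), function(pop) {
    t <- tables[[pop]]
    if (!nrow(t)) return(NULL)
    locus <- if (is.function(locus_map)) vapply(t$allele, locus_map, "")
    else if (!is.null(locus_map)) unname(locus_map[t$allele])
    else sprintf("%s:%dkb", t$contig, (t$site - 1) %/% 1000)
    data.frame(population = pop, allele = t$allele, locus = locus,
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, per_pop)
  count_sorted <- function(key) {
    n <- tapply(d$population, d[[key]], function(p) length(unique(p)))
    out <- data.frame(key = names(n), n_populations = as.integer(n),
                      stringsAsFactors = FALSE)
    names(out)[1] <- key
    out[order(-out$n_populations, out[[key]]), , drop = FALSE]
  }
  list(alleles = count_sorted("allele"), loci = count_sorted("locus"))
}

#' Detect clonal-interference events at shared loci
#'
#' An interference event is a (locus, timepoint) at which two or more
#' distinct derived alleles are simultaneously detected at or above
#' `detect_threshold`.
#'
#' @param table A `trajectory_table` for one population.
#' @param locus_map Named vector allele -> locus (default: contig + 1 kb
#'   window, as in [parallelism()]).
#' @param detect_threshold Detection cutoff.
#' @return List with `events` (locus, timepoint, n_alleles, alleles,
#'   frequencies), `per_locus` counts, and `max_alleles` (largest number
#'   of co-detected alleles at any locus/timepoint).
#' @export
detect_clonal_interference <- function(table, locus_map = NULL,
                                       detect_threshold = 0.02) {
  m <- traj_freq_matrix(table)
  locus <- if (!is.null(locus_map)) unname(locus_map[table$allele])
  else sprintf("%s:%dkb", table$contig, (table$site - 1) %/% 1000)
  events <- list()
  for (lc in unique(locus)) {
    rows <- which(locus == lc)
    if (length(rows) < 2) next
    for (tp in colnames(m)) {
      f <- m[rows, tp]
      det <- !is.na(f) & f >= detect_threshold
      if (sum(det) >= 2)
        events[[length(events) + 1L]] <- data.frame(
          locus = lc, timepoint = as.numeric(tp),
          n_alleles = sum(det),
          alleles = paste(table$allele[rows][det], collapse = ","),
          frequencies = paste(signif(f[det], 3), collapse = ","),
          stringsAsFactors = FALSE)
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(locus = character(0), timepoint = numeric(0),
               n_alleles = integer(0), alleles = character(0),
               frequencies = character(0))
  per_locus <- if (nrow(events))
    stats::aggregate(timepoint ~ locus, events, length) else
      data.frame(locus = character(0), timepoint = integer(0))
  names(per_locus)[2] <- "n_events"
  list(events = events, per_locus = per_locus,
       max_alleles = if (nrow(events)) max(events$n_alleles) else 0L)
}

#' Export a long-format Muller (fish plot) table
#'
#' Lineage nesting is inferred by a containment heuristic: B nests in A
#' iff B's frequency never exceeds A's at any shared non-NA timepoint and
#' B first appears no earlier than A; among admissible parents the one
#' with the smallest frequency envelope is chosen. Unresolved lineages
#' attach to the root. Sibling frequencies exceeding their parent are
#' clipped with a warning.
#'
#' @param table A classified `trajectory_table`.
#' @param detect_threshold Frequencies below this are treated as 0 in
#'   the export (undetected stays 0 for plotting).
#' @return Data frame (timepoint, lineage, parent, frequency).
#' @export
muller_export <- function(table, detect_threshold = 0.02) {
  m <- traj_freq_matrix(table)
  tps <- as.numeric(colnames(m))
  n <- nrow(m)
  first_seen <- apply(m, 1, function(f) {
    ix <- which(!is.na(f) & f >= detect_threshold)
    if (length(ix)) ix[1] else Inf
  })
  parent <- rep("root", n)
  if (n > 1) {
    for (b in seq_len(n)) {
      cands <- c()
      for (a in seq_len(n)) {
        if (a == b || first_seen[b] < first_seen[a]) next
        shared <- !is.na(m[a, ]) & !is.na(m[b, ])
        if (!any(shared)) next
        if (all(m[b, shared] <= m[a, shared] + 1e-9)) cands <- c(cands, a)
      }
      if (length(cands)) {
        env <- vapply(cands, function(a) sum(m[a, ], na.rm = TRUE), 0)
        parent[b] <- rownames(m)[cands[which.min(env)]]
      }
    }
  }
  f0 <- m
  f0[is.na(f0)] <- 0
  # clip siblings that exceed their parent
  clipped <- FALSE
  for (tp in seq_along(tps)) {
    for (pa in unique(parent[parent != "root"])) {
      kids <- which(parent == pa)
      pf <- f0[pa, tp]
      if (sum(f0[kids, tp]) > pf + 1e-9) {
        f0[kids, tp] <- f0[kids, tp] * pf / sum(f0[kids, tp])
        clipped <- TRUE
      }
    }
  }
  if (clipped) warning("sibling frequencies exceeded parent; clipped")
  out <- data.frame(
    timepoint = rep(tps, each = n),
    lineage = rep(rownames(m), length(tps)),
    parent = rep(parent, length(tps)),
    frequency = as.vector(f0), stringsAsFactors = FALSE)
  out[order(out$timepoint, out$lineage), , drop = FALSE]
}
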