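#' Maximum-parsimony dating of miRNA family origins
#'
#' A family's phyletic profile (present/absent/unknown at each tip) is mapped
#' onto the species tree and the minimum number of state changes (gains and
#' losses at unit cost) is found by dynamic programming. The origin age is the
#' oldest node on the root-to-focal path that is "present" in a most
#' parsimonious reconstruction; ties between equally parsimonious origins are
#' broken toward the root by default (oldest origin, flagged ambiguous).
#'
#' @name age_inference
NULL

# states: 1 = absent, 2 = present
STATE_ABSENT <- 1L
STATE_PRESENT <- 2L

profile_allowed <- function(phy, profile) {
  # allowed[node, state]: is `state` permitted at `node`? Tips constrained by
  # the profile ("unknown" allows both); internals free unless forced later.
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  allowed <- matrix(TRUE, nn, 2)
  st <- profile[phy$tip.label]
  if (anyNA(st)) {
    abort(paste0("profile missing state for tip(s): ",
                 paste(phy$tip.label[is.na(st)], collapse = ", ")))
  }
  allowed[1:ntip, STATE_ABSENT] <- st != "present"
  allowed[1:ntip, STATE_PRESENT] <- st != "absent"
  allowed
}

# Sankoff down-pass under unit gain/loss cost. Returns the (nodes x 2) matrix
# of minimal subtree costs conditional on the node's state.
sankoff_down <- function(phy, allowed) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  down <- matrix(Inf, nn, 2)
  down[1:ntip, ][allowed[1:ntip, ]] <- 0
  edge <- ape::reorder.phylo(phy, "postorder")$edge
  acc <- matrix(0, nn, 2)
  done <- rep(FALSE, nn)
  done[1:ntip] <- TRUE
  finalize <- function(v) {
    down[v, 1] <<- if (allowed[v, 1]) acc[v, 1] else Inf
    down[v, 2] <<- if (allowed[v, 2]) acc[v, 2] else Inf
    done[v] <<- TRUE
  }
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1]; ch <- edge[i, 2]
    # postorder: all of ch's own child edges precede this one
    if (!done[ch]) finalize(ch)
    # min over child state t of down[ch,t] + cost(s,t), for s = 1,2
    acc[p, 1] <- acc[p, 1] + min(down[ch, 1], down[ch, 2] + 1)
    acc[p, 2] <- acc[p, 2] + min(down[ch, 1] + 1, down[ch, 2])
  }
  finalize(ntip + 1L)  # root
  down
}

# Up-pass: up[v,s] = minimal cost of the tree outside v's subtree given v has
# state s. total[v,s] = down + up; states attaining the global minimum at a
# node form its MPR set.
sankoff_up <- function(phy, allowed, down) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  root <- ntip + 1L
  up <- matrix(Inf, nn, 2)
  up[root, ] <- ifelse(allowed[root, ], 0, Inf)
  edge <- ape::reorder.phylo(phy, "postorder")$edge
  # preorder: reverse postorder of edges
  for (i in rev(seq_len(nrow(edge)))) {
    p <- edge[i, 1]; ch <- edge[i, 2]
    sibs <- edge[edge[, 1] == p, 2]
    sibs <- sibs[sibs != ch]
    for (t in 1:2) {
      best <- Inf
      for (s in 1:2) {
        if (!allowed[p, s]) next
        v <- up[p, s] + (if (s == t) 0 else 1)
        for (sb in sibs) v <- v + min(down[sb, 1] + (s != 1), down[sb, 2] + (s != 2))
        best <- min(best, v)
      }
      up[ch, t] <- best
    }
  }
  up
}

#' Minimum state changes for one phyletic profile
#'
#' @param tree a [species_tree()].
#' @param profile named character vector (or single profile row) giving
#'   `present`/`absent`/`unknown` per tip.
#' @return a list with `change_count` (minimal number of gains + losses) and
#'   `ancestral_states`, a tibble giving, per internal node, whether `absent`
#'   and/or `present` occur in at least one most parsimonious reconstruction.
#' @export
min_changes <- function(tree, profile) {
  profile <- as_profile_vector(profile, tree)
  phy <- tree$phylo
  allowed <- profile_allowed(phy, profile)
  down <- sankoff_down(phy, allowed)
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  cost <- min(down[root, ])
  up <- sankoff_up(phy, allowed, down)
  total <- down + up
  internal <- (ntip + 1L):(ntip + phy$Nnode)
  states <- tibble(
    node = internal,
    absent = total[internal, STATE_ABSENT] <= cost,
    present = total[internal, STATE_PRESENT] <= cost
  )
  list(change_count = cost, ancestral_states = states)
}

as_profile_vector <- function(profile, tree) {
  tips <- tree$phylo$tip.label
  if (is.data.frame(profile)) {
    if (nrow(profile) != 1) abort("expected a single profile row")
    profile <- unlist(profile[, intersect(names(profile), tips)])
  }
  if (is.null(names(profile))) abort("profile must be named by species")
  miss <- setdiff(tips, names(profile))
  if (length(miss)) {
    abort(paste0("profile missing tip(s): ", paste(miss, collapse = ", ")))
  }
  v <- as.character(profile[tips])
  names(v) <- tips
  bad <- !v %in% c("present", "absent", "unknown")
  if (any(bad)) abort(paste0("invalid profile state: ", paste(unique(v[bad]), collapse = ", ")))
  v
}

# Minimal cost when the origin is fixed at path rank r: the r-th path node is
# forced present and every older path node forced absent (r = 0 forces the
# whole path absent: focal-tip-only origin).
forced_origin_cost <- function(phy, allowed, path_nodes, r) {
  a <- allowed
  if (r > 0) a[path_nodes[r], STATE_ABSENT] <- FALSE
  if (r < length(path_nodes)) {
    older <- path_nodes[(r + 1):length(path_nodes)]
    a[older, STATE_PRESENT] <- FALSE
  }
  down <- sankoff_down(phy, a)
  min(down[length(phy$tip.label) + 1L, ])
}

#' Assign an origin age to one family
#'
#' Scans every candidate origin on the root-to-focal path, computing the
#' minimal change count with the origin fixed there (the candidate node forced
#' present, all older path nodes forced absent). Candidates attaining the
#' global minimum are the equally parsimonious origins; `tie_break` selects
#' which is reported and the `ambiguous` flag records that a choice was made.
#'
#' @param tree a [species_tree()].
#' @param profile named state vector; focal tip must be `present`.
#' @param tie_break `"oldest"` (toward the root, default) or `"youngest"`.
#' @param method `"parsimony"` (unit-cost gains and losses) or `"dollo"`
#'   (single gain at the MRCA of present tips, losses counted).
#' @return a one-row tibble: `age_index`, `age_label`, `change_count`,
#'   `ambiguous`.
#' @export
assign_age <- function(tree, profile, tie_break = c("oldest", "youngest"),
                       method = c("parsimony", "dollo")) {
  tie_break <- match.arg(tie_break)
  method <- match.arg(method)
  profile <- as_profile_vector(profile, tree)
  if (profile[tree$focal] != "present") {
    abort(paste0("focal tip '", tree$focal, "' must be present for age inference"))
  }
  phy <- tree$phylo
  k <- nrow(tree$path)
  if (method == "dollo") {
    return(dollo_age(tree, profile))
  }
  allowed <- profile_allowed(phy, profile)
  costs <- vapply(0:k, function(r) forced_origin_cost(phy, allowed, tree$path$node, r),
                  numeric(1))
  best <- min(costs)
  cand <- which(costs == best) - 1L
  idx <- if (tie_break == "oldest") max(cand) else min(cand)
  tibble(
    age_index = idx,
    age_label = paste0("t", idx),
    change_count = best,
    ambiguous = length(cand) > 1
  )
}

dollo_age <- function(tree, profile) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  present <- which(profile[phy$tip.label] == "present")
  mrca <- if (length(present) == 1) present else ape::getMRCA(phy, present)
  idx <- if (mrca <= ntip) 0L else match(mrca, tree$path$node)
  if (is.na(idx)) {
    # MRCA off the focal path cannot happen when the focal tip is present
    abort("origin MRCA not on the focal path")
  }
  losses <- count_dollo_losses(phy, profile, mrca)
  tibble(
    age_index = as.integer(idx),
    age_label = paste0("t", idx),
    change_count = 1L + losses,
    ambiguous = FALSE
  )
}

# A maximal clade under the origin whose tips are all non-present and include
# at least one firm "absent" costs one loss; all-unknown clades are free.
count_dollo_losses <- function(phy, profile, origin) {
  ntip <- length(phy$tip.label)
  st <- profile[phy$tip.label]
  kids <- function(v) phy$edge[phy$edge[, 1] == v, 2]
  rec <- function(v) {
    if (v <= ntip) {
      s <- st[v]
      return(list(all_non_present = s != "present", has_absent = s == "absent", losses = 0L))
    }
    parts <- lapply(kids(v), rec)
    anp <- all(vapply(parts, `[[`, TRUE, "all_non_present"))
    ha <- any(vapply(parts, `[[`, TRUE, "has_absent"))
    sub <- sum(vapply(parts, `[[`, 0L, "losses"))
    if (anp) return(list(all_non_present = TRUE, has_absent = ha, losses = 0L))
    # children that are entirely non-present with a firm absence lose here
    for (i in seq_along(parts)) {
      if (parts[[i]]$all_non_present && parts[[i]]$has_absent) sub <- sub + 1L
    }
    list(all_non_present = FALSE, has_absent = ha, losses = sub)
  }
  rec(origin)$losses
}

#' Assign ages to every family in a presence matrix
#'
#' @param tree a [species_tree()].
#' @param profiles tibble of profiles as from [read_presence_matrix()].
#' @inheritParams assign_age
#' @return a tibble: `family`, `age_index`, `age_label`, `change_count`,
#'   `ambiguous`.
#' @export
assign_ages <- function(tree, profiles, tie_break = c("oldest", "youngest"),
                        method = c("parsimony", "dollo")) {
  tie_break <- match.arg(tie_break)
  method <- match.arg(method)
  tips <- tree$phylo$tip.label
  rows <- purrr::map(seq_len(nrow(profiles)), function(i) {
    p <- unlist(profiles[i, tips])
    assign_age(tree, p, tie_break = tie_break, method = method)
  })
  dplyr::bind_cols(tibble(family = profiles$family), dplyr::bind_rows(rows))
}

#' Collapse age groups with a merge map
#'
#' @param assignments tibble with an `age_index` column (from [assign_ages()]).
#' @param merge_map named list of integer vectors partitioning `0..K`, e.g.
#'   `list(young = 0:3, middle = 4:5, old = 6:7)`.
#' @return the assignments with a `group` column added.
#' @export
bin_groups <- function(assignments, merge_map) {
  idx <- sort(unlist(merge_map))
  k <- max(idx)
  if (any(duplicated(idx))) abort("merge_map groups overlap")
  if (!identical(as.integer(idx), 0:k)) {
    abort("merge_map must partition 0..K with no gaps")
  }
  if (any(!assignments$age_index %in% idx)) {
    abort("age index outside merge_map range")
  }
  lut <- unlist(lapply(names(merge_map), function(g) setNames(rep(g, length(merge_map[[g]])),
                                                              merge_map[[g]])))
  mutate(assignments, group = unname(lut[as.character(.data$age_index)]))
}

#' The default three-group merge map
#'
#' Young (t0-t3, post primate-rodent split), middle (t4-t5) and old (t6-t7).
#' @param k number of internal nodes on the focal path (7 for the default tree).
#' @export
default_merge_map <- function(k = 7) {
  if (k != 7) abort("default merge map is defined for the 8-interval tree")
  list(young = 0:3, middle = 4:5, old = 6:7)
}
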