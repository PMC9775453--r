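# Macrocycle annotation: locate glucopyranose rings, order them by their
# glycosidic linkage, and map chemical roles (C1..C6, O2..O6) to atoms.
#
# Numbering convention (documented, and shared with the builders): O4(n) is
# the glycosidic oxygen bonded to C4(n) of its own residue and to C1(n+1) of
# the next residue, so the flanking near-coplanar quadruple of residue n is
# O4(n-1), C1(n), C4(n), O4(n).

BOND_CUTOFF <- 1.8   # heavy-atom bond distance, Angstrom

#' Cyclodextrin host object
#'
#' Created by [annotate_cd()] or [build_ideal_cd()]; holds the Cartesian
#' coordinates of the parent structure plus, per glucose residue, a named
#' map from chemical role to atom index.
#'
#' @name cd_host
#' @return `cd_host` objects have fields `residues` (list of 7 named integer
#'   vectors), `xyz` (all-atom coordinate matrix), `atoms` (atom table),
#'   `substitution`, and `id`.
NULL

new_cd_host <- function(residues, xyz, atoms, substitution, id = 1L) {
  stopifnot(length(residues) == 7)
  for (r in residues)
    if (!all(c("C1", "C2", "C3", "C4", "C5", "O4", "O5") %in% names(r)))
      stop("each residue needs at least C1-C5, O4 and O5 roles")
  structure(list(residues = residues, xyz = xyz, atoms = atoms,
                 substitution = substitution, id = id),
            class = "cd_host")
}

#' @export
print.cd_host <- function(x, ...) {
  cat(sprintf("Cyclodextrin host #%s: 7 glucose residues, substitution = %s\n",
              x$id, x$substitution))
  invisible(x)
}

# Coordinates of one role across all 7 residues (7 x 3 matrix) or of a
# single residue's role (length-3 vector).
host_role_coords <- function(host, role, residue = NULL) {
  if (is.null(residue)) {
    idx <- vapply(host$residues, function(r) {
      if (!role %in% names(r)) NA_integer_ else r[[role]]
    }, integer(1))
    if (anyNA(idx))
      stop("role ", role, " missing in residue ", which(is.na(idx))[1])
    m <- host$xyz[idx, , drop = FALSE]
    rownames(m) <- NULL
    m
  } else {
    r <- host$residues[[residue]]
    if (!role %in% names(r))
      stop("role ", role, " missing in residue ", residue)
    as.numeric(host$xyz[r[[role]], ])
  }
}

# All atom indices belonging to a host (roles plus substituents).
host_atom_indices <- function(host) {
  sort(unique(unlist(host$residues, use.names = FALSE)))
}

# Pairwise bond list (i, j) of heavy atoms within cutoff.
bond_pairs <- function(xyz, elements, cutoff = BOND_CUTOFF) {
  heavy <- which(toupper(elements) != "H")
  if (length(heavy) < 2) return(matrix(integer(0), 0, 2))
  d <- as.matrix(stats::dist(xyz[heavy, , drop = FALSE]))
  hits <- which(d > 0 & d < cutoff, arr.ind = TRUE)
  hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
  cbind(heavy[hits[, 1]], heavy[hits[, 2]])
}

adjacency_list <- function(n, bonds) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# Locate pyranose rings: 6-cycles with exactly one ring oxygen.
find_pyranose_rings <- function(xyz, elements, adj) {
  is_O <- toupper(elements) == "O"
  is_C <- toupper(elements) == "C"
  rings <- list()
  seen <- character(0)
  for (o in which(is_O)) {
    cn <- adj[[o]][is_C[adj[[o]]]]
    if (length(cn) < 2) next
    for (a in cn) for (b in cn) {
      if (a >= b) next
      # path a - x - y - z - b avoiding o, all carbons
      for (x in adj[[a]]) {
        if (!is_C[x] || x %in% c(o, b)) next
        for (z in adj[[b]]) {
          if (!is_C[z] || z %in% c(o, a, x)) next
          y <- intersect(adj[[x]], adj[[z]])
          y <- y[is_C[y] & !(y %in% c(o, a, b, x, z))]
          for (yy in y) {
            ring <- c(o, a, x, yy, z, b)
            key <- paste(sort(ring), collapse = "-")
            if (!key %in% seen) {
              seen <- c(seen, key)
              rings[[length(rings) + 1L]] <- ring
            }
          }
        }
      }
    }
  }
  rings
}

# Assign glucose roles within one pyranose ring (indices into xyz).
assign_ring_roles <- function(ring, adj, elements) {
  is_O <- toupper(elements) == "O"
  is_C <- toupper(elements) == "C"
  o5 <- ring[1]
  anomeric <- ring[c(2, 6)]   # the two ring carbons bonded to O5
  exo_O <- vapply(anomeric, function(c)
    any(is_O[setdiff(adj[[c]], ring)]), logical(1))
  if (sum(exo_O) == 0) return(NULL)          # not a glycoside ring
  c1 <- if (sum(exo_O) == 2) {
    # both carbons carry an exocyclic O (e.g. unmethylated C5-O? unusual);
    # take the one whose exocyclic O bridges to another carbon (glycosidic)
    bridges <- vapply(anomeric, function(c) {
      os <- setdiff(adj[[c]], ring); os <- os[is_O[os]]
      any(vapply(os, function(o) sum(is_C[adj[[o]]]) >= 2, logical(1)))
    }, logical(1))
    if (any(bridges)) anomeric[which(bridges)[1]] else anomeric[1]
  } else anomeric[which(exo_O)]
  c5 <- setdiff(anomeric, c1)
  # walk the ring from C1 away from O5
  nxt <- function(cur, prev) setdiff(intersect(adj[[cur]], ring), c(prev, cur))
  c2 <- setdiff(intersect(adj[[c1]], ring), o5)
  if (length(c2) != 1) return(NULL)
  c3 <- nxt(c2, c1)
  if (length(c3) != 1) return(NULL)
  c4 <- nxt(c3, c2)
  if (length(c4) != 1 || length(c5) != 1) return(NULL)
  roles <- c(O5 = o5, C1 = c1, C2 = c2, C3 = c3, C4 = c4, C5 = c5)
  exo <- function(c, el) {
    cand <- setdiff(adj[[c]], ring)
    cand[el[cand]][1]
  }
  o2 <- exo(c2, is_O); if (!is.na(o2)) roles["O2"] <- o2
  o3 <- exo(c3, is_O); if (!is.na(o3)) roles["O3"] <- o3
  o4 <- exo(c4, is_O)
  if (is.na(o4)) return(NULL)                # C4 must carry the glycosidic O
  roles["O4"] <- o4
  c6 <- exo(c5, is_C)
  if (!is.na(c6)) {
    roles["C6"] <- c6
    o6cand <- setdiff(adj[[c6]], c(c5))
    o6cand <- o6cand[is_O[o6cand]]
    if (length(o6cand)) roles["O6"] <- o6cand[1]
  }
  roles
}

# Substituent carbons attached to O2/O3/O6, for substitution inference.
rim_substituents <- function(roles, adj, elements) {
  is_C <- toupper(elements) == "C"
  out <- list()
  for (o in c("O2", "O3", "O6")) {
    if (!o %in% names(roles)) next
    ring_c <- roles[[sub("O", "C", o)]]
    cand <- setdiff(adj[[roles[[o]]]],
                    c(ring_c, if ("C6" %in% names(roles)) roles[["C6"]]))
    cand <- cand[is_C[cand]]
    if (length(cand)) out[[o]] <- cand
  }
  out
}

# Attach substituent roles and infer the substitution pattern for an
# ordered 7-residue role list; shared by both annotation schemes.
finish_host <- function(residues, xyz, atoms, adj, id) {
  subs <- lapply(residues, rim_substituents, adj = adj,
                 elements = atoms$element)
  rim_ox <- unlist(lapply(residues, function(r)
    r[intersect(c("O2", "O3", "O6"), names(r))]), use.names = FALSE)
  for (i in seq_along(residues)) {
    s <- subs[[i]]
    if (length(s)) {
      v <- unlist(s)
      names(v) <- paste0("sub_", rep(names(s), lengths(s)))
      residues[[i]] <- c(residues[[i]], v)
    }
  }
  new_cd_host(residues, xyz, atoms,
              substitution = infer_substitution(subs, adj, atoms$element,
                                                rim_ox),
              id = id)
}

infer_substitution <- function(sub_pattern, adj, elements, rim_oxygens) {
  # sub_pattern: list (per residue) of lists O2/O3/O6 -> substituent C idx
  has <- sapply(c("O2", "O3", "O6"), function(o)
    mean(vapply(sub_pattern, function(s) !is.null(s[[o]]), logical(1))))
  # a methyl substituent carbon has no chain continuation; hydroxypropyl
  # continues into carbons that are themselves not ether-bonded to a rim
  # oxygen (which screens out incidental methyl-methyl near-contacts)
  is_C <- toupper(elements) == "C"
  hp <- any(vapply(sub_pattern, function(s) {
    any(vapply(unlist(s), function(c) {
      chain <- adj[[c]][is_C[adj[[c]]]]
      chain <- chain[!vapply(chain, function(k)
        any(adj[[k]] %in% rim_oxygens), logical(1))]
      length(chain) > 0
    }, logical(1)))
  }, logical(1)))
  if (hp) return("hydroxypropyl")
  if (has["O2"] > 0.5 && has["O3"] > 0.5 && has["O6"] > 0.5) return("permethyl")
  if (has["O2"] > 0.5 && has["O6"] > 0.5) return("2,6-di-O-methyl")
  if (sum(has) > 0) return("2,6-di-O-methyl")
  "native"
}

#' Annotate cyclodextrin macrocycles in a structure
#'
#' Finds every complete glucose heptamer and returns one [cd_host] per
#' macrocycle, residues ordered by the glycosidic linkage.  Role assignment
#' uses heavy-atom connectivity (bond cutoff 1.8 Angstrom), which copes with
#' the heterogeneous label dialects of deposited CIFs; a label-driven scheme
#' (`"labels"`) is available when labels follow `<role><residue>` (e.g.
#' `C11` .. `O67`) or `<role>_<residue>` patterns.
#'
#' @param structure A [crystal_structure()].
#' @param scheme `"auto"` (labels first, fall back to connectivity),
#'   `"labels"`, or `"connectivity"`.
#' @param alt_site Disorder site to analyse; atoms whose `alt_site` differs
#'   from it are dropped (atoms with no alt tag are always kept).
#' @return A list of [cd_host] objects.
#' @export
annotate_cd <- function(structure, scheme = c("auto", "connectivity", "labels"),
                        alt_site = NULL) {
  scheme <- match.arg(scheme)
  structure <- as_cartesian(structure)
  keep <- if (is.null(alt_site)) rep(TRUE, nrow(structure$atoms)) else
    is.na(structure$atoms$alt_site) | structure$atoms$alt_site == alt_site
  atoms <- structure$atoms[keep, , drop = FALSE]
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (scheme == "labels" || scheme == "auto") {
    hosts <- try(annotate_by_labels(atoms, xyz), silent = TRUE)
    if (!inherits(hosts, "try-error") && length(hosts)) return(hosts)
    if (scheme == "labels")
      stop("label-based annotation failed; labels are ambiguous - use an ",
           "explicit scheme or connectivity: ",
           attr(hosts, "condition")$message)
  }
  annotate_by_connectivity(atoms, xyz)
}

annotate_by_connectivity <- function(atoms, xyz) {
  bonds <- bond_pairs(xyz, atoms$element)
  adj <- adjacency_list(nrow(atoms), bonds)
  rings <- find_pyranose_rings(xyz, atoms$element, adj)
  role_sets <- Filter(Negate(is.null),
                      lapply(rings, assign_ring_roles, adj = adj,
                             elements = atoms$element))
  if (!length(role_sets))
    stop("no glucopyranose rings found by connectivity")
  # successor: residue whose C1 is bonded to this residue's O4
  c1s <- vapply(role_sets, function(r) r[["C1"]], integer(1))
  succ <- vapply(role_sets, function(r) {
    hit <- which(c1s %in% adj[[r[["O4"]]]])
    if (length(hit) == 1) hit else NA_integer_
  }, integer(1))
  # walk closed chains
  unvisited <- seq_along(role_sets)
  hosts <- list()
  while (length(unvisited)) {
    start <- unvisited[1]
    chain <- start
    cur <- succ[start]
    while (!is.na(cur) && !(cur %in% chain) && length(chain) < 50) {
      chain <- c(chain, cur)
      cur <- succ[cur]
    }
    closed <- !is.na(cur) && cur == start
    unvisited <- setdiff(unvisited, chain)
    if (!closed) next                       # open oligomer fragment: skip
    if (length(chain) != 7)
      stop("candidate macrocycle has ", length(chain),
           " glucose units; expected 7")
    residues <- role_sets[chain]
    hosts[[length(hosts) + 1L]] <-
      finish_host(residues, xyz, atoms, adj, id = length(hosts) + 1L)
  }
  if (!length(hosts))
    stop("no closed glucose heptamer found")
  hosts
}

annotate_by_labels <- function(atoms, xyz) {
  lab <- toupper(atoms$label)
  # suffix style: role labels C1..C6/O2..O6 with residue_id distinguishing
  m1 <- regexec("^([CO][1-6])(?:_([0-9]+))?$", lab)
  g <- regmatches(lab, m1)
  ok <- lengths(g) == 3
  if (!any(ok)) stop("no role-pattern labels")
  role <- vapply(g[ok], `[`, "", 2)
  suffix <- vapply(g[ok], `[`, "", 3)
  res <- ifelse(suffix == "", NA_integer_, suppressWarnings(as.integer(suffix)))
  if (anyNA(res)) {
    rid <- atoms$residue_id[ok]
    if (length(unique(rid)) < 7) {
      # concatenated crystallographic style: last digit = residue
      m2 <- regexec("^([CO][1-6])([1-9])$", lab)
      g2 <- regmatches(lab, m2)
      ok <- lengths(g2) == 3
      if (!any(ok)) stop("labels carry no residue information")
      role <- vapply(g2[ok], `[`, "", 2)
      res <- as.integer(vapply(g2[ok], `[`, "", 3))
    } else res <- rid
  }
  idx <- which(ok)
  resids <- sort(unique(res))
  if (length(resids) %% 7 != 0) stop("found ", length(resids),
                                     " labelled residues; expected 7 per host")
  n_hosts <- length(resids) / 7
  # substituent atoms carry no role labels: find them by connectivity
  adj <- adjacency_list(nrow(atoms), bond_pairs(xyz, atoms$element))
  hosts <- list()
  for (h in seq_len(n_hosts)) {
    rset <- resids[((h - 1) * 7 + 1):(h * 7)]
    residues <- lapply(rset, function(rn) {
      sel <- res == rn
      v <- idx[sel]
      names(v) <- role[sel]
      if (anyDuplicated(names(v))) stop("ambiguous duplicate role labels in residue ", rn)
      v
    })
    hosts[[h]] <- finish_host(residues, xyz, atoms, adj, id = h)
  }
  # label order may not follow the glycosidic walk; validate geometry loosely
  for (host in hosts) {
    o4 <- host_role_coords(host, "O4")
    d <- sqrt(rowSums((o4 - o4[c(2:7, 1), ])^2))
    if (any(d > 12)) stop("label-derived residue order is not a closed ring")
  }
  hosts
}
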