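## Pedigree data model and the structural machinery behind the
## Elston-Stewart peeling likelihood: validation, decomposition into nuclear
## families, loop detection/breaking for consanguineous pedigrees, and the
## peeling schedule handed to the C++ engine.

#' Construct a pedigree
#'
#' @param family_id Family identifier (string).
#' @param id Character vector of individual ids (unique within the family).
#' @param father,mother Character vectors of parent ids; `NA` or `"0"` for
#'   founders.  Either both parents are present or both absent.
#' @param sex Optional vector (`1`/`"male"`, `2`/`"female"`, else unknown).
#' @param sequenced Logical vector; unsequenced members carry flat genotype
#'   likelihoods in all computations.
#' @return Object of class `"pedigree"`: list with `fam` and a data frame
#'   `members` (columns `id`, `father`, `mother`, `sex`, `sequenced`,
#'   `founder`, `gl_source`).
#' @export
#' @examples
#' trio <- pedigree("f1", id = c("dad", "mum", "kid"),
#'                  father = c(NA, NA, "dad"), mother = c(NA, NA, "mum"))
#' trio
pedigree <- function(family_id, id, father = NA, mother = NA,
                     sex = NULL, sequenced = TRUE) {
  n <- length(id)
  id <- as.character(id)
  norm <- function(x) {
    x <- rep_len(as.character(x), n)
    x[x %in% c("0", "", "NA")] <- NA_character_
    x
  }
  father <- norm(father)
  mother <- norm(mother)
  if (anyDuplicated(id)) stop("duplicate individual ids in family ", family_id)
  if (any(is.na(father) != is.na(mother))) {
    stop("family ", family_id,
         ": individuals must have either both parents or neither")
  }
  bad <- !is.na(father) & !(father %in% id)
  bad <- bad | (!is.na(mother) & !(mother %in% id))
  if (any(bad)) {
    stop("family ", family_id, ": unresolvable parent id(s) for ",
         paste(id[bad], collapse = ", "))
  }
  if (is.null(sex)) sex <- rep("unknown", n)
  sex <- rep_len(as.character(sex), n)
  sex[sex %in% c("1", "male", "M")] <- "male"
  sex[sex %in% c("2", "female", "F")] <- "female"
  sex[!sex %in% c("male", "female")] <- "unknown"
  members <- data.frame(id = id, father = father, mother = mother,
                        sex = sex,
                        sequenced = rep_len(as.logical(sequenced), n),
                        founder = is.na(father),
                        gl_source = id,
                        stringsAsFactors = FALSE)
  ped <- structure(list(fam = as.character(family_id), members = members),
                   class = "pedigree")
  check_acyclic(ped)
  ped
}

#' @export
print.pedigree <- function(x, ...) {
  m <- x$members
  cat("<pedigree> family", x$fam, "-", nrow(m), "members,",
      sum(m$founder), "founders,", sum(!m$founder), "non-founders\n")
  invisible(x)
}

## error if some individual is its own ancestor
check_acyclic <- function(ped) {
  m <- ped$members
  fa <- match(m$father, m$id)
  mo <- match(m$mother, m$id)
  n <- nrow(m)
  state <- integer(n)  # 0 unvisited, 1 in stack, 2 done
  visit <- function(i) {
    if (state[i] == 1L) {
      stop("family ", ped$fam, ": cyclic pedigree at individual ", m$id[i])
    }
    if (state[i] == 2L) return(invisible())
    state[i] <<- 1L
    for (p in c(fa[i], mo[i])) if (!is.na(p)) visit(p)
    state[i] <<- 2L
  }
  for (i in seq_len(n)) visit(i)
  invisible(ped)
}

#' Parse a 6-column PED file
#'
#' Whitespace-delimited columns: family, individual, father, mother, sex,
#' phenotype; `0` denotes a missing parent.  Lines starting with `#` are
#' skipped.
#'
#' @param path Path to a PED file, or a character vector of PED lines via
#'   `text`.
#' @param text Optional PED content as a character scalar/vector (overrides
#'   `path`).
#' @param sequenced_ids Optional character vector of individual ids present
#'   in the genotype-likelihood input; members absent from it are flagged
#'   unsequenced.
#' @return Named list of [pedigree()] objects, one per family id.
#' @export
parse_ped <- function(path = NULL, text = NULL, sequenced_ids = NULL) {
  lines <- if (!is.null(text)) {
    unlist(strsplit(text, "\n", fixed = TRUE))
  } else {
    readLines(path)
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty PED input")
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop("PED line(s) with fewer than 6 columns: ",
         paste(which(nf < 6L), collapse = ", "))
  }
  tab <- do.call(rbind, lapply(fields, function(f) f[1:6]))
  fams <- unique(tab[, 1L])
  peds <- lapply(fams, function(f) {
    rows <- tab[tab[, 1L] == f, , drop = FALSE]
    seq_flag <- if (is.null(sequenced_ids)) TRUE else rows[, 2L] %in% sequenced_ids
    pedigree(f, id = rows[, 2L], father = rows[, 3L], mother = rows[, 4L],
             sex = rows[, 5L], sequenced = seq_flag)
  })
  stats::setNames(peds, fams)
}

#' Write pedigrees to a 6-column PED file
#'
#' @param peds A [pedigree()] or list of pedigrees.
#' @param path Output path.
#' @export
write_ped <- function(peds, path) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  rows <- lapply(peds, function(p) {
    m <- p$members
    data.frame(fam = p$fam, id = m$id,
               father = ifelse(is.na(m$father), "0", m$father),
               mother = ifelse(is.na(m$mother), "0", m$mother),
               sex = c(male = 1L, female = 2L, unknown = 0L)[m$sex],
               pheno = 0L)
  })
  utils::write.table(do.call(rbind, rows), path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(path)
}

## nuclear families: one entry per unique parent couple, with integer member
## indices into ped$members
nuclear_families <- function(ped) {
  m <- ped$members
  kids <- which(!m$founder)
  if (!length(kids)) return(list())
  key <- paste(m$father[kids], m$mother[kids])
  split_kids <- split(kids, key)
  lapply(split_kids, function(ch) {
    i <- ch[1L]
    list(father = match(m$father[i], m$id),
         mother = match(m$mother[i], m$id),
         children = as.integer(ch))
  })
}

#' Detect and break consanguinity loops
#'
#' The peeling engine requires the graph of nuclear families to be a forest.
#' Marriage/inbreeding loops (e.g. a first-cousin marriage) are cut by
#' duplicating one individual per loop: the original keeps its parent links,
#' while a clone (id suffixed `"_dup"`) takes over the spouse/offspring role
#' in the offending nuclear family and is treated as a founder.  Both share
#' the same sequence data (`gl_source`), which is the classic loop-breaking
#' approximation: the likelihood is no longer exact, but family information
#' is retained.
#'
#' @param ped A [pedigree()].
#' @return List with elements `pedigree` (loop-free) and `map` (data frame
#'   with columns `original`, `clone`; zero rows if the input had no loops).
#' @export
detect_and_break_loops <- function(ped) {
  map <- data.frame(original = character(), clone = character(),
                    stringsAsFactors = FALSE)
  repeat {
    m <- ped$members
    nf <- nuclear_families(ped)
    if (length(nf) < 2L) break
    ## union-find over nuclear families
    parent <- seq_along(nf)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    ## families per individual, child-family first so clones are always
    ## created in a family where the individual is a parent
    fam_of <- lapply(seq_len(nrow(m)), function(i) {
      as_child <- which(vapply(nf, function(f) i %in% f$children, logical(1)))
      as_parent <- which(vapply(nf, function(f) {
        f$father == i || f$mother == i
      }, logical(1)))
      c(as_child, as_parent)
    })
    broke <- FALSE
    for (i in seq_len(nrow(m))) {
      fs <- fam_of[[i]]
      if (length(fs) < 2L) next
      for (k in 2:length(fs)) {
        ra <- find(fs[1L])
        rb <- find(fs[k])
        if (ra == rb) {
          ## loop: clone individual i out of its parent role in family fs[k]
          ped <- clone_member(ped, i, nf[[fs[k]]])
          map <- rbind(map, data.frame(
            original = m$id[i],
            clone = ped$members$id[nrow(ped$members)],
            stringsAsFactors = FALSE))
          broke <- TRUE
          break
        }
        parent[rb] <- ra
      }
      if (broke) break
    }
    if (!broke) break
  }
  list(pedigree = ped, map = map)
}

## replace individual `i`'s parent slot in nuclear family `fam` by a founder
## clone sharing the same sequence data
clone_member <- function(ped, i, fam) {
  m <- ped$members
  orig <- m$id[i]
  clone_id <- orig
  repeat {
    clone_id <- paste0(clone_id, "_dup")
    if (!clone_id %in% m$id) break
  }
  kids <- fam$children
  if (fam$father == i) m$father[kids] <- clone_id
  if (fam$mother == i) m$mother[kids] <- clone_id
  m <- rbind(m, data.frame(id = clone_id, father = NA_character_,
                           mother = NA_character_, sex = m$sex[i],
                           sequenced = m$sequenced[i], founder = TRUE,
                           gl_source = m$gl_source[i],
                           stringsAsFactors = FALSE))
  ped$members <- m
  check_acyclic(ped)
  ped
}

## Peeling schedule for the C++ engine.  Returns list(data_fam, n, glrow,
## out_col, founder, sched, singles): `sched` is a list of integer vectors
## c(connector, father, mother, children...), leaves first, connector = 0
## for the root family of each connected component; `glrow` maps each member
## (loop-breaking clones included) to the column of its sequence data, and
## `out_col` maps original members to an output column (0 for clones).
peeling_plan <- function(ped, data_fam = 1L) {
  m <- ped$members
  n <- nrow(m)
  nf <- nuclear_families(ped)
  ## gl_source refers to original ids; data columns are the non-clone
  ## members in their original order
  originals <- which(m$id == m$gl_source)
  glrow <- match(m$gl_source, m$id[originals])
  out_col <- ifelse(m$id == m$gl_source, glrow, 0L)
  founder <- as.integer(m$founder)

  if (!length(nf)) {
    return(list(data_fam = as.integer(data_fam), n = n,
                glrow = as.integer(glrow), out_col = as.integer(out_col),
                founder = founder, sched = list(), singles = seq_len(n)))
  }
  ## adjacency between families via shared individuals
  memb <- lapply(nf, function(f) c(f$father, f$mother, f$children))
  in_family <- lapply(seq_len(n), function(i) {
    which(vapply(memb, function(v) i %in% v, logical(1)))
  })
  nfam <- length(nf)
  adj <- vector("list", nfam)
  via <- vector("list", nfam)
  parent <- seq_len(nfam)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    fs <- in_family[[i]]
    if (length(fs) < 2L) next
    for (k in 2:length(fs)) {
      a <- fs[1L]
      b <- fs[k]
      if (find(a) == find(b)) {
        stop("pedigree ", ped$fam, " contains loops; apply ",
             "detect_and_break_loops() first")
      }
      parent[find(b)] <- find(a)
      adj[[a]] <- c(adj[[a]], b)
      via[[a]] <- c(via[[a]], i)
      adj[[b]] <- c(adj[[b]], a)
      via[[b]] <- c(via[[b]], i)
    }
  }
  ## BFS per component; peel order is reverse BFS
  visited <- logical(nfam)
  sched <- list()
  for (root in seq_len(nfam)) {
    if (visited[root]) next
    order <- integer()
    connector <- integer()
    queue <- root
    visited[root] <- TRUE
    conn <- c(0L)
    while (length(queue)) {
      f <- queue[1L]
      queue <- queue[-1L]
      order <- c(order, f)
      connector <- c(connector, conn[1L])
      conn <- conn[-1L]
      nb <- adj[[f]]
      vi <- via[[f]]
      for (j in seq_along(nb)) {
        if (!visited[nb[j]]) {
          visited[nb[j]] <- TRUE
          queue <- c(queue, nb[j])
          conn <- c(conn, vi[j])
        }
      }
    }
    for (k in rev(seq_along(order))) {
      f <- nf[[order[k]]]
      sched[[length(sched) + 1L]] <-
        as.integer(c(connector[k], f$father, f$mother, f$children))
    }
  }
  in_any <- sort(unique(unlist(memb)))
  singles <- setdiff(seq_len(n), in_any)
  list(data_fam = as.integer(data_fam), n = n, glrow = as.integer(glrow),
       out_col = as.integer(out_col), founder = founder,
       sched = sched, singles = as.integer(singles))
}

## ---- canonical pedigree builders used by simulations and tests ----------

#' Canonical pedigree structures
#'
#' Builders for the family structures used throughout the simulations:
#' a parents-offspring trio, a nuclear family with `n_children` sequenced
#' siblings (optionally dropping parents), the 10-person 3-generation
#' extended pedigree (4 founders: one grandparental couple plus two
#' married-in spouses; 6 non-founders: two middle-generation siblings, three
#' grandchildren on one side and one on the other), and a 10-person
#' 3-generation pedigree containing a first-cousin marriage (for
#' loop-breaking).
#'
#' @param family_id Family identifier.
#' @param n_children Number of children for `pedigree_nuclear()`.
#' @param parents How many parents are included (2, 1 or 0) in
#'   `pedigree_nuclear()`; omitted parents are absent from the pedigree
#'   entirely (children become founders linked as siblings only if at least
#'   one parent remains; with 0 parents, unsequenced placeholder parents are
#'   added so sibs stay related).
#' @return A [pedigree()].
#' @export
pedigree_trio <- function(family_id = "trio") {
  pedigree(family_id, id = c("fa", "mo", "ch"),
           father = c(NA, NA, "fa"), mother = c(NA, NA, "mo"),
           sex = c("male", "female", "unknown"))
}

#' @rdname pedigree_trio
#' @export
pedigree_nuclear <- function(family_id = "nuc", n_children = 2L,
                             parents = 2L) {
  kids <- paste0("ch", seq_len(n_children))
  ids <- c("fa", "mo", kids)
  ped <- pedigree(family_id, id = ids,
                  father = c(NA, NA, rep("fa", n_children)),
                  mother = c(NA, NA, rep("mo", n_children)),
                  sex = c("male", "female", rep("unknown", n_children)),
                  sequenced = c(parents >= 1L, parents >= 2L,
                                rep(TRUE, n_children)))
  ## convention: with 1 parent the mother is unsequenced, with 0 both are;
  ## placeholder parents keep the sibship linked
  ped
}

#' @rdname pedigree_trio
#' @export
pedigree_3gen <- function(family_id = "gen3") {
  ids <- c("I-1", "I-2", "II-1", "II-2", "II-3", "II-4",
           "III-1", "III-2", "III-3", "III-4")
  fa <- c(NA, NA, NA, "I-1", NA, "I-1",
          "II-1", "II-1", "II-1", "II-3")
  mo <- c(NA, NA, NA, "I-2", NA, "I-2",
          "II-2", "II-2", "II-2", "II-4")
  sex <- c("male", "female", "male", "female", "male", "female",
           rep("unknown", 4))
  pedigree(family_id, id = ids, father = fa, mother = mo, sex = sex)
}

#' @rdname pedigree_trio
#' @export
pedigree_first_cousin <- function(family_id = "cousin") {
  ids <- c("I-1", "I-2", "II-1", "II-2", "II-3", "II-4",
           "III-1", "III-2", "IV-1", "IV-2")
  fa <- c(NA, NA, NA, "I-1", "I-1", NA,
          "II-1", "II-3", "III-1", "III-1")
  mo <- c(NA, NA, NA, "I-2", "I-2", NA,
          "II-2", "II-4", "III-2", "III-2")
  sex <- c("male", "female", "male", "female", "male", "female",
           "male", "female", "unknown", "unknown")
  pedigree(family_id, id = ids, father = fa, mother = mo, sex = sex)
}
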