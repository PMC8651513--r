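## GROMACS-dialect topology I/O: the [atoms] section of an .itp file.
## Only the charge column is ever rewritten; everything else round-trips.

## Locate the [atoms] section; returns indices of its data lines.
itp_atoms_lines <- function(lines) {
  sec <- grep("^\\s*\\[\\s*atoms\\s*\\]\\s*(;.*)?$", lines)
  if (length(sec) == 0) {
    stop("format error: no [atoms] section found")
  }
  start <- sec[1] + 1
  end <- length(lines)
  nxt <- grep("^\\s*\\[", lines)
  nxt <- nxt[nxt > sec[1]]
  if (length(nxt)) end <- nxt[1] - 1
  if (start > end) return(integer(0))
  idx <- start:end
  keep <- !grepl("^\\s*(;.*)?$", lines[idx])   # drop blanks and comments
  idx[keep]
}

## Split an [atoms] data line into fields, ignoring a trailing ';' comment.
itp_fields <- function(line) {
  code <- sub(";.*$", "", line)
  strsplit(trimws(code), "\\s+")[[1]]
}

#' Read per-atom partial charges from a GROMACS topology
#'
#' Parses the `[atoms]` section (columns nr/type/resnr/residue/atom/cgnr/
#' charge, optionally mass), returning a [charge_set()] in file order with
#' type and mass kept as opaque annotations so that [apply_charges()] can
#' round-trip the file. Structure that the file format cannot express --
#' equivalence groups, frozen atoms, the declared net charge and reference
#' charges -- comes from an optional sidecar config (see
#' [read_charge_config()]).
#'
#' @param path Path to an .itp/.top file containing an `[atoms]` section.
#' @param config Optional sidecar: a path to a TOML/JSON file or a list as
#'   returned by [read_charge_config()].
#' @param repair If `TRUE`, spread any small net-charge residual uniformly
#'   over non-frozen atoms instead of erroring (off by default).
#' @param net_tol Net-charge tolerance in e.
#' @return A `charge_set`.
#' @export
read_itp_charges <- function(path, config = NULL, repair = FALSE,
                             net_tol = 1e-9) {
  lines <- readLines(path, warn = FALSE)
  idx <- itp_atoms_lines(lines)
  if (length(idx) == 0) stop("format error: [atoms] section is empty")
  recs <- lapply(idx, function(i) {
    f <- itp_fields(lines[i])
    if (length(f) < 7) {
      stop(sprintf("parse error on line %d: expected >= 7 fields, got %d",
                   i, length(f)))
    }
    ch <- suppressWarnings(as.numeric(f[7]))
    if (is.na(ch)) {
      stop(sprintf("parse error on line %d: non-numeric charge '%s'",
                   i, f[7]))
    }
    list(nr = f[1], type = f[2], resnr = f[3], residue = f[4],
         atom = f[5], cgnr = f[6], charge = ch,
         mass = if (length(f) >= 8) f[8] else NA_character_)
  })
  nrs <- vapply(recs, `[[`, character(1), "nr")
  if (anyDuplicated(nrs)) {
    stop("validation error: duplicate atom numbers: ",
         paste(unique(nrs[duplicated(nrs)]), collapse = ", "))
  }
  atoms <- vapply(recs, `[[`, character(1), "atom")
  charges <- vapply(recs, `[[`, numeric(1), "charge")
  ann <- data.frame(
    nr = nrs,
    type = vapply(recs, `[[`, character(1), "type"),
    resnr = vapply(recs, `[[`, character(1), "resnr"),
    residue = vapply(recs, `[[`, character(1), "residue"),
    cgnr = vapply(recs, `[[`, character(1), "cgnr"),
    mass = vapply(recs, `[[`, character(1), "mass"),
    line = idx,
    stringsAsFactors = FALSE)

  if (is.character(config)) config <- read_charge_config(config)
  groups <- seq_along(atoms)
  frozen <- rep(FALSE, length(atoms))
  net <- 0
  refq <- charges
  if (!is.null(config)) {
    if (!is.null(config$net_charge)) net <- config$net_charge
    if (!is.null(config$equivalence_groups)) {
      for (grp in config$equivalence_groups) {
        pos <- match(grp, atoms)
        if (anyNA(pos)) {
          stop("validation error: equivalence group names atoms absent from ",
               "topology: ", paste(grp[is.na(pos)], collapse = ", "))
        }
        groups[pos] <- min(groups[pos])
      }
    }
    if (!is.null(config$frozen)) {
      pos <- match(config$frozen, atoms)
      if (anyNA(pos)) {
        stop("validation error: frozen list names atoms absent from ",
             "topology: ", paste(config$frozen[is.na(pos)], collapse = ", "))
      }
      frozen[pos] <- TRUE
    }
    if (!is.null(config$reference_charges)) {
      rq <- config$reference_charges
      pos <- match(names(rq), atoms)
      if (anyNA(pos)) {
        stop("validation error: reference charges name unknown atoms: ",
             paste(names(rq)[is.na(pos)], collapse = ", "))
      }
      refq[pos] <- as.numeric(rq)
    }
  }
  cs <- charge_set(atoms, charges, reference_charges = refq, groups = groups,
                   frozen = frozen, net_charge = net, annotations = ann,
                   validate = FALSE)
  if (repair) cs <- repair_net_charge(cs)
  validate_charge_set(cs, net_tol = net_tol)
  cs
}

#' Write a charge set into a topology file
#'
#' Rewrites only the charge column of the `[atoms]` section (6 decimal
#' places, right-aligned to the original field width where it fits); every
#' other byte of the file is preserved. Refuses to write a set that violates
#' the declared net charge.
#'
#' @param base Path to the template topology.
#' @param new A `charge_set` whose `atom_names` match the `[atoms]` section
#'   one-to-one, in order.
#' @param out Output path (may equal `base`).
#' @param net_tol Net-charge tolerance in e.
#' @return `out`, invisibly.
#' @export
apply_charges <- function(base, new, out, net_tol = 1e-9) {
  stopifnot(inherits(new, "charge_set"))
  net <- sum(new$charges)
  if (abs(net - new$net_charge) > net_tol) {
    stop(sprintf(
      "validation error: refusing to write charges with net %+.9f e (declared %+g e)",
      net, new$net_charge))
  }
  lines <- readLines(base, warn = FALSE)
  idx <- itp_atoms_lines(lines)
  atoms <- vapply(idx, function(i) itp_fields(lines[i])[5], character(1))
  if (length(atoms) != length(new$atom_names) ||
      !identical(atoms, new$atom_names)) {
    offenders <- union(setdiff(atoms, new$atom_names),
                       setdiff(new$atom_names, atoms))
    if (length(offenders) == 0) offenders <- "(ordering differs)"
    stop("validation error: atom names do not match topology: ",
         paste(offenders, collapse = ", "))
  }
  for (k in seq_along(idx)) {
    i <- idx[k]
    line <- lines[i]
    code_end <- regexpr(";", line, fixed = TRUE)
    code <- if (code_end > 0) substr(line, 1, code_end - 1) else line
    m <- gregexpr("\\S+", code)[[1]]
    if (length(m) < 7) stop("parse error on line ", i)
    start <- m[7]
    width <- attr(m, "match.length")[7]
    val <- sprintf("%.6f", new$charges[k])
    val <- formatC(val, width = width)      # right-align; grow if needed
    lines[i] <- paste0(substr(line, 1, start - 1), val,
                       substr(line, start + width, nchar(line)))
  }
  writeLines(lines, out)
  invisible(out)
}

#' Read a sidecar charge-structure config
#'
#' The sidecar declares what the topology format cannot: `equivalence_groups`
#' (array of arrays of atom names), `frozen` (array of atom names),
#' `net_charge` (number), and optionally `reference_charges` (table of atom
#' name to charge). Accepted formats: JSON, or a flat TOML subset (string /
#' number / boolean scalars, flat and nested arrays, `[table]` headers).
#'
#' @param path Path to a .toml or .json file.
#' @return A named list.
#' @export
read_charge_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    parse_toml_subset(readLines(path, warn = FALSE))
  }
  if (!is.null(cfg$equivalence_groups)) {
    eg <- cfg$equivalence_groups
    if (!is.list(eg)) eg <- list(eg)
    cfg$equivalence_groups <- lapply(eg, as.character)
  }
  if (!is.null(cfg$frozen)) cfg$frozen <- as.character(cfg$frozen)
  if (!is.null(cfg$reference_charges)) {
    cfg$reference_charges <- unlist(cfg$reference_charges)
  }
  cfg
}

## Minimal TOML subset parser: 'key = value' with string/number/boolean
## scalars, flat arrays, one level of nested arrays, and [table] headers.
## Covers the sidecar schema; not a general TOML implementation.
parse_toml_subset <- function(lines) {
  out <- list()
  table <- NULL
  buf <- ""
  pending_key <- NULL
  for (raw in lines) {
    line <- sub("(^|[^\\\\])#.*$", "\\1", raw)   # strip comments
    line <- trimws(line)
    if (nzchar(buf)) { line <- paste(buf, line); buf <- "" }
    if (!nzchar(line)) next
    th <- regmatches(line, regexec("^\\[([^]]+)\\]$", line))[[1]]
    if (length(th) == 2) { table <- trimws(th[2]); next }
    kv <- regmatches(line, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.*)$",
                                   line))[[1]]
    if (length(kv) != 3) stop("toml parse error near: ", raw)
    key <- kv[2]; val <- kv[3]
    ## multiline array: keep buffering until brackets balance
    no_str <- gsub('"[^"]*"', "", val)
    if (lengths(regmatches(no_str, gregexpr("\\[", no_str))) >
        lengths(regmatches(no_str, gregexpr("\\]", no_str)))) {
      buf <- line
      next
    }
    parsed <- toml_value(val)
    if (is.null(table)) out[[key]] <- parsed
    else out[[table]][[key]] <- parsed
  }
  if (nzchar(buf)) stop("toml parse error: unterminated array")
  out
}

toml_value <- function(s) {
  s <- trimws(s)
  if (startsWith(s, "[")) return(toml_array(s))
  if (grepl('^".*"$', s)) return(gsub('^"|"$', "", s))
  if (s %in% c("true", "false")) return(s == "true")
  num <- suppressWarnings(as.numeric(s))
  if (!is.na(num)) return(num)
  stop("toml parse error: unsupported value: ", s)
}

toml_array <- function(s) {
  inner <- sub("^\\[", "", sub("\\]$", "", trimws(s)))
  if (!nzchar(trimws(inner))) return(list())
  ## split on top-level commas
  depth <- 0; parts <- character(0); cur <- ""
  in_str <- FALSE
  for (ch in strsplit(inner, "")[[1]]) {
    if (ch == '"') in_str <- !in_str
    if (!in_str) {
      if (ch == "[") depth <- depth + 1
      if (ch == "]") depth <- depth - 1
      if (ch == "," && depth == 0) {
        parts <- c(parts, cur); cur <- ""
        next
      }
    }
    cur <- paste0(cur, ch)
  }
  if (nzchar(trimws(cur))) parts <- c(parts, cur)
  vals <- lapply(trimws(parts), toml_value)
  if (all(vapply(vals, function(v) is.atomic(v) && length(v) == 1,
                 logical(1)))) {
    unlist(vals)
  } else {
    vals
  }
}
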