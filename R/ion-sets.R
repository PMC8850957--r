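#' Diagnostic ion sets
#'
#' An ion set names the unit-mass channels summed by an estimator, with
#' optional syringyl/guaiacyl sublabels used by the S/G ratio. Members must
#' be unique integers within m/z 30-450; violations are rejected at
#' construction.
#'
#' The shipped sets are the standard py-MBMS diagnostic channels:
#' * `lignin_ions()`: 120, 124 (G), 137 (G), 138 (G), 150 (G), 152, 154 (S),
#'   164 (G), 167 (S), 168 (S), 178 (G), 180, 181, 182 (S), 194 (S),
#'   208 (S), 210 (S). The unlabeled members count toward lignin content but
#'   toward neither monolignol class.
#' * `c6_ions()`: 57, 60, 73, 98, 126, 144 (glucose/cellulose pyrolyzates;
#'   126 is associated with hydroxymethylfurfural).
#' * `c5_ions()`: 57, 73, 85, 96, 114 (xylose/xylan pyrolyzates; 114 derives
#'   from a xylose lactone). The overlap with the C6 set (57, 73) is kept as
#'   is: each estimator is applied independently.
#'
#' @param name Set label.
#' @param members Integer m/z values.
#' @param sublabels Optional character vector (`"S"`, `"G"` or `"none"`),
#'   either named by m/z or parallel to `members`.
#' @return An `ion_set` object.
#' @examples
#' sg_members(lignin_ions())
#' @export
ion_set <- function(name, members, sublabels = NULL) {
  members <- as.integer(members)
  if (anyDuplicated(members) > 0) {
    abort("ion set members must be unique", class = "pymbms_error_ion_set")
  }
  if (length(members) > 0 && (min(members) < MZ_MIN || max(members) > MZ_MAX)) {
    abort("ion set members must lie within m/z 30..450",
          class = "pymbms_error_ion_set")
  }
  if (is.null(sublabels)) {
    sublabels <- setNames(rep("none", length(members)), members)
  } else {
    if (is.null(names(sublabels))) {
      stopifnot(length(sublabels) == length(members))
      names(sublabels) <- members
    }
    full <- setNames(rep("none", length(members)), members)
    full[names(sublabels)] <- sublabels
    sublabels <- full
    if (!all(sublabels %in% c("S", "G", "none"))) {
      abort("sublabels must be 'S', 'G' or 'none'", class = "pymbms_error_ion_set")
    }
  }
  structure(
    list(name = name, members = members, sublabels = sublabels),
    class = "ion_set"
  )
}

#' @export
print.ion_set <- function(x, ...) {
  lab <- ifelse(x$sublabels == "none", "", paste0(" (", x$sublabels, ")"))
  cat("Ion set '", x$name, "': m/z ",
      paste0(x$members, lab, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname ion_set
#' @export
lignin_ions <- function() default_ion_sets()$lignin

#' @rdname ion_set
#' @export
c6_ions <- function() default_ion_sets()$c6

#' @rdname ion_set
#' @export
c5_ions <- function() default_ion_sets()$c5

#' Members of an ion set by sublabel
#' @param ions An [ion_set()].
#' @param label `"S"` or `"G"`.
#' @return Integer m/z members carrying the label.
#' @export
sg_members <- function(ions, label = c("S", "G")) {
  label <- match.arg(label)
  ions$members[ions$sublabels[as.character(ions$members)] == label]
}

#' Read ion sets from a config file
#'
#' Ion sets ship as a versioned YAML file so alternative channel choices can
#' be swapped in; `default_ion_sets()` loads the packaged copy.
#'
#' @param path YAML file: a named map of sets, each with `members` and
#'   optional `sublabels` (map of m/z to S/G).
#' @return A named list of [ion_set()] objects.
#' @export
read_ion_sets <- function(path) {
  raw <- yaml::read_yaml(path)
  sets <- raw[setdiff(names(raw), "version")]
  out <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    sub <- if (!is.null(s$sublabels)) unlist(s$sublabels)
    ion_set(nm, unlist(s$members), sub)
  })
  setNames(out, names(sets))
}

#' @rdname read_ion_sets
#' @export
default_ion_sets <- function() {
  read_ion_sets(system.file("extdata", "ion_sets.yml", package = "pymbms",
                            mustWork = TRUE))
}
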