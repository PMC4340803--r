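# The packaged hospital example: a patient enters the hospital, is admitted
# to a ward, and the clinical process in the ward repeatedly assigns
# procedures (each later executed, carrying its procedure code and cost) and
# sets diagnoses (during which a second doctor may be consulted if a second
# opinion is necessary), until the doctor interrupts the ward process by
# discharging or transferring the patient.
#
# The attribute set extends the minimal diagram with the fields every query
# construct needs (age, surname, diagnosis, cost, total_expenses); the
# enumeration "pCode" supplies procedure codes in the codificator style of
# clinical coding systems.

#' The built-in hospital process model
#'
#' Nine activities: the master "Patient enters the hospital" (age, surname),
#' the ward admission, the aggregate "Clinical process in ward"
#' (total_expenses) with components "Doctor assigns procedure"
#' (procedure_code, cardinality `*`) and "Doctor sets diagnosis" (diagnosis,
#' cardinality `*`), the execution of each assigned procedure
#' (procedure_code, cost), the second-opinion consultation reached through
#' an extension point, and the discharge/transfer activities reached through
#' interruption flows out of the ward process.
#'
#' @return a valid `medmod_model`.
#' @examples
#' m <- demo_model()
#' validate_model(m)   # zero rows
#' @export
demo_model <- function() {
  medmod_model(
    name = "hospital",
    enumerations = list(
      pCode = c("XR", "CT", "US", "LAB", "ECG"),
      dCode = c("Chickenpox", "Pneumonia", "Stroke", "Influenza",
                "Appendicitis", "Fracture")),
    activities = list(
      medmod_activity("Patient enters the hospital",
                      list(medmod_attribute("age", "Integer"),
                           medmod_attribute("surname", "String")),
                      master = TRUE),
      medmod_activity("Patient admitted to hospital ward"),
      medmod_activity("Clinical process in ward",
                      list(medmod_attribute("total_expenses", "Real"))),
      medmod_activity("Doctor assigns procedure",
                      list(medmod_attribute("procedure_code", "pCode"))),
      medmod_activity("Procedure is executed",
                      list(medmod_attribute("procedure_code", "pCode"),
                           medmod_attribute("cost", "Real"))),
      medmod_activity("Doctor sets diagnosis",
                      list(medmod_attribute("diagnosis", "dCode"))),
      medmod_activity("Patient consulted by second doctor"),
      medmod_activity("Patient discharged from hospital"),
      medmod_activity("Patient transferred to another ward")),
    edges = list(
      medmod_edge("follows", "Patient enters the hospital",
                  "Patient admitted to hospital ward"),
      medmod_edge("follows", "Patient admitted to hospital ward",
                  "Clinical process in ward"),
      medmod_edge("composition", "Clinical process in ward",
                  "Doctor assigns procedure", cardinality = "*"),
      medmod_edge("composition", "Clinical process in ward",
                  "Doctor sets diagnosis", cardinality = "*"),
      medmod_edge("follows", "Doctor assigns procedure",
                  "Procedure is executed"),
      medmod_edge("extension", "Doctor sets diagnosis",
                  "Patient consulted by second doctor",
                  extension_point = "second opinion is necessary"),
      medmod_edge("interruption", "Clinical process in ward",
                  "Patient discharged from hospital"),
      medmod_edge("interruption", "Clinical process in ward",
                  "Patient transferred to another ward")))
}

#' Default simulation configuration for the demo model
#'
#' The stated world of the synthetic generator: admissions arrive with
#' exponential inter-arrival times (mean 30 min); a ward episode assigns
#' 1–5 procedures (mean 2.9, each later executed at a cost of 20–300
#' currency units) and sets 1–4 diagnoses (mean 2.3); a second opinion is
#' sought with probability 0.3 per diagnosis; the ward process ends by
#' discharge (weight 0.7) or transfer (weight 0.3). These rates put the
#' expected slice size near 12.8 instances, so 5000 slices yield roughly
#' 64,000 instances — the experimental scale the engine is exercised at.
#'
#' @param n_slices number of patient transactions.
#' @param seed RNG seed.
#' @param time_origin ISO-8601 start of the observation window.
#' @return a `medmod_sim_config` for [simulate_trace()].
#' @export
demo_config <- function(n_slices, seed = 1L,
                        time_origin = "2012-01-01T08:00:00Z") {
  surnames <- c("Smith", "Jones", "Berzins", "Ozols", "Kalnins", "Liepa",
                "Martin", "Garcia", "Novak", "Petrov", "Andersen", "Keller")
  sim_config(
    n_slices = n_slices, seed = seed, time_origin = time_origin,
    inter_arrival = dist_exponential(1 / 1800),
    branch_weights = list(
      "Clinical process in ward" = c(
        "Patient discharged from hospital" = 0.7,
        "Patient transferred to another ward" = 0.3)),
    extension_prob = list(
      "Doctor sets diagnosis->Patient consulted by second doctor" = 0.3),
    composition_counts = list(
      "Clinical process in ward->Doctor assigns procedure" =
        dist_categorical(1:5, c(0.15, 0.25, 0.30, 0.15, 0.15)),
      "Clinical process in ward->Doctor sets diagnosis" =
        dist_categorical(1:4, c(0.20, 0.40, 0.30, 0.10))),
    durations = list(
      "Patient enters the hospital" = dist_uniform(600, 3600),
      "Patient admitted to hospital ward" = dist_uniform(900, 7200),
      "Doctor assigns procedure" = dist_uniform(300, 1800),
      "Procedure is executed" = dist_uniform(900, 5400),
      "Doctor sets diagnosis" = dist_uniform(600, 3600),
      "Patient consulted by second doctor" = dist_uniform(900, 3600),
      "Patient discharged from hospital" = dist_uniform(600, 1800),
      "Patient transferred to another ward" = dist_uniform(600, 1800)),
    attributes = list(
      "Patient enters the hospital.age" = dist_uniform_int(1, 95),
      "Patient enters the hospital.surname" = dist_categorical(surnames),
      "Clinical process in ward.total_expenses" =
        dist_uniform_int(200, 8000),
      "Doctor assigns procedure.procedure_code" =
        dist_categorical(c("XR", "CT", "US", "LAB", "ECG")),
      "Procedure is executed.cost" = dist_uniform_int(20, 300),
      "Doctor sets diagnosis.diagnosis" = dist_categorical(
        c("Chickenpox", "Pneumonia", "Stroke", "Influenza",
          "Appendicitis", "Fracture"),
        c(0.10, 0.25, 0.10, 0.25, 0.15, 0.15))),
    inherit = list(
      "Doctor assigns procedure->Procedure is executed" = "procedure_code"))
}
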