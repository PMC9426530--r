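# Default pathogen keyword configuration.
# A genome is labelled "pathogen" when any of the recognised Biosample fields
# (general description, isolation source, isolation site, host, environmental
# medium, sample type) contains one of these case-insensitive substrings.
# The list approximates manual curation of isolation metadata and is meant to
# be edited for a given study.
keywords:
  - pathogen
  - pathogenic
  - patient with
  - diseased
  - disease
  - infection
  - infected
  - lesion
  - clinical isolate
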