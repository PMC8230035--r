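# Default rubric lexicon. These term lists are this package's own,
# versioned resource: they seed each detector with the worked phrases the
# rubric's item descriptions give (e.g. "committed suicide" for
# criminalizing language, the accept/reject mood terms for the
# mental-health link) and expand them conservatively with common Indian
# English news phrasing. Entries are lowercase; entries prefixed "re:" are
# regular expressions (used for phone numbers). Edit and re-version freely;
# every report records the version it was produced with.
version: "1.0.0"

# sentences "about the case": used by the <50%-content screening rule
case_terms:
  - suicide
  - suicides
  - kills self
  - killed himself
  - killed herself
  - kill himself
  - kill herself
  - ends life
  - ended his life
  - ended her life
  - end his life
  - end her life
  - took his own life
  - took her own life
  - take his own life
  - take her own life
  - died by suicide
  - attempted suicide
  - suicide attempt

criminalizing_phrases:
  - committed suicide
  - commit suicide
  - commits suicide
  - committing suicide

method_terms:
  - hanging
  - hanged
  - hangs
  - poison
  - poisoning
  - poisoned
  - overdose
  - drowned
  - drowning
  - jumped
  - jumping
  - immolated
  - immolation
  - electrocuted
  - shot himself
  - shot herself
  - slit his wrists
  - slit her wrists
  - consumed pesticide

method_detail_terms:
  - kerosene
  - celphos
  - rope
  - noose
  - ceiling fan
  - dupatta
  - sleeping pills
  - rat poison
  - phenyl
  - acid
  - revolver
  - pistol
  - blade
  - insecticide
  - bedsheet

site_terms:
  - bridge
  - flyover
  - railway track
  - railway tracks
  - terrace
  - rooftop
  - canal
  - lake
  - reservoir
  - water tank
  - hostel room
  - quarry

location_prepositions:
  - at
  - near
  - behind
  - beneath
  - under
  - beside
  - overlooking
  - from

single_factor_markers:
  - due to
  - because of
  - sole reason
  - only reason
  - solely because
  - the reason was
  - triggered by
  - blamed on
  - attributed the suicide to
  - took the extreme step after

speculation_markers:
  - reason may be
  - may have been
  - might have been
  - might be
  - not yet known
  - yet to be ascertained
  - under investigation
  - suspected
  - possibly
  - uncertainties about the cause
  - unclear why
  - speculation

stressor_nouns:
  - debt
  - debts
  - failure
  - exam
  - exams
  - harassment
  - scolding
  - scolded
  - divorce
  - illness
  - unemployment
  - losses
  - lockdown
  - dispute
  - breakup

reason_cues:
  - after
  - over
  - due to
  - following
  - blamed on

helpline_names:
  - sneha
  - aasra
  - icall
  - sumaitri
  - vandrevala foundation
  - kiran
  - lifeline
  - helpline
  - crisis line

helpline_phone_patterns:
  - "re:(?<![0-9])[0-9]{3,5}-[0-9]{4,8}(?![0-9])"
  - "re:(?<![0-9])[0-9]{4}-[0-9]{4}-[0-9]{3,4}(?![0-9])"
  - "re:(?<![0-9])[0-9]{8,12}(?![0-9])"

mental_health_accept_terms:
  - depressed
  - depression
  - anxious
  - anxiety
  - panic
  - trauma
  - disturbed
  - distraught
  - bipolar disorder
  - schizophrenia
  - mental illness
  - psychiatric illness
  - mental disorder
  - post-traumatic stress

mental_health_reject_terms:
  - crazy
  - mental
  - stressed
  - unhappy
  - mad
  - insane
  - lunatic
  - tension
  - upset

substance_struggle_terms:
  - alcohol addiction
  - drug addiction
  - alcoholism
  - substance abuse
  - drug abuse
  - alcohol abuse
  - addicted to
  - battled addiction
  - struggle with alcohol
  - struggled with alcohol
  - struggling with alcohol
  - de-addiction
  - drug habit

intoxication_only_terms:
  - drunk
  - intoxicated
  - inebriated
  - under the influence
  - consumed liquor
  - in an inebriated state

expert_role_terms:
  - psychiatrist
  - psychologist
  - mental health professional
  - suicide prevention expert
  - counsellor
  - counselor
  - therapist
  - mental health expert

attribution_cues:
  - said
  - says
  - stated
  - according to
  - told
  - noted
  - added
  - confirmed
  - observed
  - explained
  - remarked
  - warned

official_source_terms:
  - police
  - police officer
  - police officers
  - inspector
  - sub-inspector
  - constable
  - superintendent
  - magistrate
  - district collector
  - health official
  - health officials
  - medical officer
  - doctor
  - doctors
  - hospital authorities
  - government official
  - government officials
  - forensic experts
  - post-mortem report

bare_source_phrases:
  - sources
  - sources said
  - according to sources
  - sources claimed

stat_markers:
  - suicide rate
  - per 100,000
  - per lakh
  - national crime records bureau
  - ncrb
  - statistics
  - study found
  - survey found
  - percent
  - per cent

myth_markers:
  - myth
  - myths
  - misconception
  - misconceptions
  - common belief

refutation_markers:
  - "false"
  - untrue
  - not true
  - no evidence
  - debunked
  - contrary to
  - in fact
  - wrongly

prevention_markers:
  - preventable
  - can be prevented
  - prevention is possible
  - preventive measures
  - warning signs
  - reduce stigma
  - reduces stigma
  - seek help
  - help-seeking

hope_markers:
  - overcame suicidal thoughts
  - overcame his suicidal thoughts
  - overcame her suicidal thoughts
  - recovered from suicidal thoughts
  - hopeful story
  - regained hope
  - rebuilt his life
  - rebuilt her life
  - survivor of a suicide attempt

grief_terms:
  - bereaved
  - grieving
  - mourning
  - inconsolable
  - left behind
  - widow
  - widower
  - orphaned
  - condolences

note_terms:
  - suicide note
  - note
  - text message
  - text messages
  - whatsapp message
  - social media post
  - last message
  - farewell note

# screening fallback cues (heuristic; used only when no human category tag)
commentary_cues:
  - editorial
  - opinion piece
  - op-ed
  - commentary
  - world suicide prevention day

ideation_cues:
  - suicidal thoughts
  - suicidal ideation
  - contemplating suicide

bombing_cues:
  - suicide bomber
  - suicide bombing
  - suicide attack
  - suicide blast

undetermined_cues:
  - cause of death was undetermined
  - cause of death is yet to be ascertained
  - could be a homicide
  - foul play has not been ruled out
  - accidental death or suicide
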