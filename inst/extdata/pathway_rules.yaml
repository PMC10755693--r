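# Domain-signature rule sets for sulfoglycolytic / sulfolytic pathway
# classification of genome neighbourhoods.
#
# Rules are data, not code: edit tags here to match your annotation
# pipeline.  Tags are descriptive enzyme labels; substitute PFAM (or other)
# accessions if your feature tables carry them.  A pathway is called when
# at least `min_groups` of its groups are satisfied; a group is satisfied
# when at least `min_hits` features in the window carry one of its tags.
# Multi-enzyme pathways require all groups; single-signature pathways
# (SFT/SMO/SDO) require their one diagnostic enzyme.
pathways:
  sulfo-EMP:
    min_groups: 4
    groups:
      isomerase:
        tags: [SQ_isomerase]
        min_hits: 1
      kinase:
        tags: [SF_kinase]
        min_hits: 1
      aldolase:
        tags: [SFP_aldolase]
        min_hits: 1
      dehydrogenase:
        tags: [SLA_dehydrogenase]
        min_hits: 1
  sulfo-ED:
    min_groups: 4
    groups:
      dehydrogenase:
        tags: [SQ_dehydrogenase]
        min_hits: 1
      lactonase:
        tags: [SGL_lactonase]
        min_hits: 1
      dehydratase:
        tags: [SG_dehydratase]
        min_hits: 1
      aldolase:
        tags: [KDSG_aldolase]
        min_hits: 1
  sulfo-SFT:
    min_groups: 1
    groups:
      transaldolase:
        tags: [SF_transaldolase]
        min_hits: 1
  sulfo-SMO:
    min_groups: 1
    groups:
      monooxygenase:
        tags: [SQ_monooxygenase]
        min_hits: 1
  sulfo-SDO:
    min_groups: 1
    groups:
      dioxygenase:
        tags: [SQ_dioxygenase]
        min_hits: 1
# SQase family tags used for presence flags
sqase_tags:
  gh31: [GH31]
  gh188: [GH188]
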