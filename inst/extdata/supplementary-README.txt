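Drop-in location for the published supplementary NEXUS alignments
(ITS.nex, matK.nex, Acc1.nex, CEN.nex). They are not redistributed with
the package; see ?supplementary_alignment.
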