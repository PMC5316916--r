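category	count
candidate_pool	819571
panel_total	35143
codominant	15393
dominant	19750
transition	24194
transversion	10949
polymorphic_in_screen	33326
consensus_mapped	21709
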