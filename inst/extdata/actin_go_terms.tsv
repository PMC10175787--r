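go_id	name
GO:0003779	actin binding
GO:0003785	actin monomer binding
GO:0051015	actin filament binding
GO:0015629	actin cytoskeleton
GO:0030036	actin cytoskeleton organization
GO:0007015	actin filament organization
GO:0045010	actin nucleation
GO:0030041	actin filament polymerization
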