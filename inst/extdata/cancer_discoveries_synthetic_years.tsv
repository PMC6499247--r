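# Cancer-research discovery triples (A, B, C) with ontology identifiers.
# The discovery_year column is SYNTHETIC: the source table lists only the
# citing references, so a placeholder year (2012, inside the 2006-2016
# survey window) is used. Replace with true publication years for real
# time-sliced evaluation.
a_id	b_id	c_id	discovery_year	mode
PR:000001754	PR:000002307	MESH:D000236	2012	both
PR:000011331	HOC:42	PR:000005308	2012	both
PR:000001138	PR:000003107	PR:000006736	2012	both
PR:000011170	CHEBI:26523	MESH:D010190	2012	both
PR:000006066	HOC:42	MESH:D013964	2012	both
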