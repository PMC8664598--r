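item_id	text	domain	is_sleep_item
C01	Shows pleasure when s/he succeeds	competence	0
C02	Follows simple directions	competence	0
C03	Tries to help when someone is hurt	competence	0
C04	Imitates playful sounds and gestures	competence	0
C05	Plays pretend games with toys	competence	0
C06	Looks for caregiver when playing in a new place	competence	0
C07	Points to show something interesting	competence	0
C08	Hugs or feeds dolls or stuffed animals	competence	0
C09	Pays attention to a whole picture book	competence	0
C10	Greets familiar people with warmth	competence	0
C11	Takes turns in simple games	competence	0
I01	Seems nervous or fearful	internalizing	0
I02	Is worried or serious in new situations	internalizing	0
I03	Seems unhappy or sad without reason	internalizing	0
I04	Is afraid of particular places or objects	internalizing	0
I05	Does not react when hurt	internalizing	0
I06	Avoids physical contact	internalizing	0
I07	Withdraws from unfamiliar people	internalizing	0
I08	Seems anxious when away from caregiver	internalizing	0
E01	Hits, bites, or kicks other children	externalizing	0
E02	Is restless and cannot sit still	externalizing	0
E03	Is destructive with objects on purpose	externalizing	0
E04	Acts without thinking of danger	externalizing	0
E05	Demands attention constantly	externalizing	0
E06	Hits or bites the parent	externalizing	0
D01	Cries or tantrums until s/he is exhausted	dysregulation	0
D02	Has trouble adjusting to changes	dysregulation	0
D03	Often gets very upset	dysregulation	0
D04	Gags or chokes on food	dysregulation	0
D05	Refuses to eat or is very picky	dysregulation	0
D06	Cannot calm down once upset	dysregulation	0
D07	Wakes up at night and needs help to fall asleep again	dysregulation	1
D08	Has trouble falling asleep or staying asleep	dysregulation	1
O01	Stares into space for long periods	other_problem	0
O02	Repeats the same movement over and over	other_problem	0
O03	Does not make eye contact	other_problem	0
O04	Hurts self on purpose	other_problem	0
O05	Eats or drinks things that are not food	other_problem	0
O06	Seems not to hear when spoken to	other_problem	0
O07	Does not show affection to caregivers	other_problem	0
O08	Puts things in a special order over and over	other_problem	0
O09	Seems very fearful of strangers	other_problem	0
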