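# trigger	kind	day_offset (relative-date triggers)
yesterday	offset_days	-1
today	offset_days	0
tonight	offset_days	0
this morning	offset_days	0
this afternoon	offset_days	0
this evening	offset_days	0
last night	offset_days	-1
last week	offset_days	-7
a week ago	offset_days	-7
a day ago	offset_days	-1
a few days ago	phrasal	-
a couple days ago	phrasal	-
a couple of days ago	phrasal	-
several days ago	phrasal	-
a while ago	phrasal	-
the other day	phrasal	-
recently	phrasal	-
earlier this week	phrasal	-
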