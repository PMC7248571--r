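"year","index","currency","fx_rate"
1990,0.597579,"USD",1
1991,0.609531,"USD",1
1992,0.621721,"USD",1
1993,0.634156,"USD",1
1994,0.646839,"USD",1
1995,0.659776,"USD",1
1996,0.672971,"USD",1
1997,0.686431,"USD",1
1998,0.700159,"USD",1
1999,0.714163,"USD",1
2000,0.728446,"USD",1
2001,0.743015,"USD",1
2002,0.757875,"USD",1
2003,0.773033,"USD",1
2004,0.788493,"USD",1
2005,0.804263,"USD",1
2006,0.820348,"USD",1
2007,0.836755,"USD",1
2008,0.85349,"USD",1
2009,0.87056,"USD",1
2010,0.887971,"USD",1
2011,0.905731,"USD",1
2012,0.923845,"USD",1
2013,0.942322,"USD",1
2014,0.961169,"USD",1
2015,0.980392,"USD",1
2016,1,"USD",1
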