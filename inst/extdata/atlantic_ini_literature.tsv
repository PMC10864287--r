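region	recording_months	recording_years	ini_pattern_s	source
Mid-Atlantic Ridge (MARI)	Jan, Dec	1999-2000	~20	Hatch & Clark
Western Tropical North Atlantic (WTNA)	Jan, Feb, Mar, Dec	1993-1994	~12-14	Hatch & Clark
Central Western North Atlantic (CWNA)	Jan, Feb	1993-1994	~13-14	Hatch & Clark
Bermuda	All months	1958-1979 (four seasons)	~18 (Feb-Apr); ~14 (Nov-Jan)	Watkins et al.
NYB/GoM	All months	2008-2009	~15 (Mar-May); ~10 (Sep-Jan)	Morano et al.
Northwestern Atlantic (NWNA)	Jan-Apr, Nov, Dec	1994-1995; 2002-2003	~8-10; ~14-15	Hatch & Clark
GoM	Jan-Mar, Aug-Dec	2006; 2007	~15 (Jan-Mar); ~9 (Sep-Jan)	Delarue et al.
GSL	Sep-Dec	2005	~11-12 (Sep-Dec)	Delarue et al.
Davis Strait	All months	2006-2008	~13.5 (Oct-Nov)	Simon et al.
North Eastern North Atlantic (NENA)	All months	1993-1995; 1997-2002	~10-12; ~18-19	Hatch & Clark
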